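#' Confinement free energy in a square channel: de Gennes regime
#'
#' Excess free energy of a self-avoiding chain of contour length L,
#' persistence length P and width w in a square channel of side D under
#' moderate (blob) confinement: \code{dA/kT = 4.0 L (P w)^(1/3) D^(-5/3)}.
#' The numeric prefactor is an order-of-magnitude constant; when the channel
#' stands in for the interstitial volume of a post array it should not be
#' read strictly.
#'
#' @param L Contour length (sigma).
#' @param P Persistence length (sigma).
#' @param w Chain width (sigma).
#' @param D Channel side (sigma); the quasi-channel diameter d_c in an array.
#' @return Free energy excess in k_B T.
#' @export
degennes_channel_dA <- function(L, P, w, D) {
  stopifnot(all(L > 0), all(P > 0), all(w > 0), all(D > 0))
  4.0 * L * (P * w)^(1 / 3) * D^(-5 / 3)
}

#' Confinement free energy in a square channel: Odijk regime
#'
#' Strong-confinement (deflection-segment) free energy of a semiflexible
#' chain in a square channel of side \code{D < P}:
#' \code{dA/kT = 2.2072 L P^(-1/3) D^(-2/3)}.
#'
#' @inheritParams degennes_channel_dA
#' @return Free energy excess in k_B T.
#' @export
odijk_channel_dA <- function(L, P, D) {
  stopifnot(all(L > 0), all(P > 0), all(D > 0))
  2.2072 * L * P^(-1 / 3) * D^(-2 / 3)
}

#' Slit free energy from the channel expression
#'
#' A chain confined in a slit of height D has, to a good approximation, half
#' the free energy of the same chain in a square channel of side D; the
#' quasi-slit (passage aperture) free energies are the channel expressions
#' halved.
#'
#' @param channel_dA Channel free energy evaluated at the slit height.
#' @return Half the channel value.
#' @export
slit_dA <- function(channel_dA) {
  stopifnot(all(channel_dA >= 0))
  0.5 * channel_dA
}

#' Chain-length partition ratio between interstitial volumes and apertures
#'
#' At equilibrium the free energy per unit contour length of chain fragments
#' in the quasi-channels (diameter d_c) equals that in the quasi-slits
#' (height w_p); equating the per-length confinement free energies gives the
#' ratio \code{L_qc/L_qs} of chain length stored in interstitial volumes to
#' chain length in passage apertures:
#' \itemize{
#'   \item de Gennes / de Gennes: \code{(1/2) (d_c/w_p)^(5/3)},
#'   \item de Gennes / Odijk:
#'     \code{0.2759 (w_p/P)^(2/3) (w_p/w)^(1/3) (d_c/w_p)^(5/3)},
#'   \item Odijk / Odijk: \code{(1/2) (d_c/w_p)^(2/3)}.
#' }
#' Only the mixed combination depends on the chain parameters P and w. An
#' Odijk channel with a de Gennes slit (a stiff chain squeezed harder in the
#' wide space than in the narrow one) is unphysical and rejected.
#'
#' @param regime_qc Regime in the interstitial volume: \code{"degennes"} or
#'   \code{"odijk"}.
#' @param regime_qs Regime in the passage aperture.
#' @param d_c Quasi-channel diameter (sigma).
#' @param w_p Quasi-slit height (sigma).
#' @param P Persistence length (needed for the mixed combination).
#' @param w Chain width (needed for the mixed combination).
#' @return The ratio L_qc/L_qs.
#' @export
partition_ratio <- function(regime_qc = c("degennes", "odijk"),
                            regime_qs = c("degennes", "odijk"),
                            d_c, w_p, P = NULL, w = NULL) {
  regime_qc <- match.arg(regime_qc)
  regime_qs <- match.arg(regime_qs)
  stopifnot(all(d_c > 0), all(w_p > 0))
  r <- d_c / w_p
  if (regime_qc == "degennes" && regime_qs == "degennes") {
    0.5 * r^(5 / 3)
  } else if (regime_qc == "odijk" && regime_qs == "odijk") {
    0.5 * r^(2 / 3)
  } else if (regime_qc == "degennes" && regime_qs == "odijk") {
    if (is.null(P) || is.null(w))
      stop("the mixed de Gennes/Odijk ratio needs P and w")
    (1.1036 / 4.0) * (w_p / P)^(2 / 3) * (w_p / w)^(1 / 3) * r^(5 / 3)
  } else {
    stop("unsupported regime pair: Odijk interstitial with de Gennes aperture")
  }
}

#' Odijk axial extension in a narrow channel
#'
#' \code{R = L [1 - A (D/P)^(2/3)]} with A = 0.1701 (circular cross-section)
#' or 0.18274 (square), valid for \code{D < P}.
#'
#' @inheritParams degennes_channel_dA
#' @param cross_section \code{"square"} (default; matches the quasi-channel
#'   approximation) or \code{"circular"}.
#' @return Predicted extension R (sigma).
#' @export
odijk_extension <- function(L, P, D, cross_section = c("square", "circular")) {
  cross_section <- match.arg(cross_section)
  stopifnot(all(L > 0), all(P > 0), all(D > 0))
  if (any(D >= P))
    warning("Odijk extension evaluated outside its validity domain (D >= P)")
  A <- if (cross_section == "square") 0.18274 else 0.1701
  L * (1 - A * (D / P)^(2 / 3))
}

#' de Gennes axial extension in a wide channel
#'
#' \code{R = L (w P / D^2)^(1/3)}, valid for \code{D > P}.
#'
#' @inheritParams degennes_channel_dA
#' @return Predicted extension R (sigma).
#' @export
degennes_extension <- function(L, P, w, D) {
  stopifnot(all(L > 0), all(P > 0), all(w > 0), all(D > 0))
  L * (w * P / D^2)^(1 / 3)
}

#' Confinement regime of a channel
#'
#' Odijk for \code{D < P}; extended de Gennes for \code{P < D < P^2/w};
#' classic de Gennes for \code{D > P^2/w}. Boundary values resolve to the
#' stronger-confinement label.
#'
#' @param P Persistence length (sigma).
#' @param w Chain width (sigma).
#' @param D Confinement size (sigma).
#' @return Character label.
#' @export
classify_regime <- function(P, w, D) {
  stopifnot(P > 0, w > 0, all(D > 0))
  vapply(D, function(d) {
    if (d <= P) "Odijk"
    else if (d <= P^2 / w) "extended de Gennes"
    else "classic de Gennes"
  }, "")
}

#' Expected number of asymmetric blobs in the extended de Gennes regime
#'
#' Order-of-magnitude count \code{L (w^2 / (d_c^4 P))^(1/3)}; when it falls
#' below the occupation number there are too few blobs for extended-de Gennes
#' statistics to show in S(q).
#'
#' @param L Contour length (sigma).
#' @param w Chain width (sigma).
#' @param d_c Channel (interstitial) diameter (sigma).
#' @param P Persistence length (sigma).
#' @return Expected blob count.
#' @export
blob_count_extended <- function(L, w, d_c, P) {
  stopifnot(all(L > 0), all(w > 0), all(d_c > 0), all(P > 0))
  L * (w^2 / (d_c^4 * P))^(1 / 3)
}

#' Predicted S(q) slope windows for a channel-confined chain
#'
#' Assembles the wavevector intervals over which the log-log slope of the
#' single-chain structure factor is predicted, for a chain of persistence
#' length P, width w and bond length l with axial span R_s confined at size
#' D: slope -1 at monomer/persistence scales (q above 2 pi over max(P, l));
#' in the classic de Gennes regime slope -5/3 on (2 pi/D, 2 pi/P); in the
#' extended de Gennes regime slope -2 on (2 pi/(D^2 P^2/w)^(1/3), 2 pi/P);
#' slope -1 again for the linear blob array down to 2 pi/R_s; saturation
#' (slope 0) below 2 pi/R_s. In the Odijk regime the whole q > 2 pi/R_s
#' range is rod-like (-1). Empty intervals are omitted.
#'
#' @param P Persistence length (sigma).
#' @param w Chain width (sigma).
#' @param D Confinement size (sigma).
#' @param R_s Axial span (sigma).
#' @param l Bond length (sigma).
#' @return data.frame with columns \code{q_min}, \code{q_max}, \code{slope},
#'   \code{label}, ordered by decreasing q.
#' @export
slope_windows <- function(P, w, D, R_s, l = 0.97) {
  stopifnot(P > 0, w > 0, D > 0, R_s > 0, l > 0)
  regime <- classify_regime(P, w, D)
  q_sat <- 2 * pi / R_s
  rows <- list()
  add <- function(q_min, q_max, slope, label) {
    if (q_min < q_max)
      rows[[length(rows) + 1]] <<- data.frame(q_min = q_min, q_max = q_max,
                                              slope = slope, label = label)
  }
  if (regime == "Odijk") {
    add(q_sat, Inf, -1, "rod-like (Odijk)")
    add(0, q_sat, 0, "saturation")
  } else {
    q_pers <- 2 * pi / max(P, l)
    q_blob <- if (regime == "classic de Gennes") 2 * pi / D
              else 2 * pi / (D^2 * P^2 / w)^(1 / 3)
    blob_slope <- if (regime == "classic de Gennes") -5 / 3 else -2
    blob_label <- if (regime == "classic de Gennes")
      "swollen blobs (classic de Gennes)" else "asymmetric blobs (extended de Gennes)"
    add(q_pers, Inf, -1, "persistence/monomer scale")
    add(max(q_blob, q_sat), q_pers, blob_slope, blob_label)
    add(q_sat, min(q_blob, q_pers), -1, "linear blob array")
    add(0, q_sat, 0, "saturation")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regime and partition report for a geometry series
#'
#' For each array, classifies the quasi-channel (D = d_c) and quasi-slit
#' (D = w_p) regimes for a chain of the given persistence length and width,
#' and tabulates the partition ratios L_qc/L_qs for the applicable regime
#' combinations. For a semiflexible chain whose aperture is in the Odijk
#' regime, both the mixed de Gennes/Odijk and the Odijk/Odijk entries are
#' reported (which one applies in the interstitial volume depends on d_c
#' versus P).
#'
#' @param arrays List of \code{\link{post_array}} objects.
#' @param P Persistence length (sigma).
#' @param w Chain width (sigma).
#' @param file Optional CSV output path.
#' @return data.frame, one row per array.
#' @export
regime_report <- function(arrays, P, w = 0.9, file = NULL) {
  df <- do.call(rbind, lapply(arrays, function(a) {
    ch <- classify_regime(P, w, a$d_c)
    sl <- classify_regime(P, w, a$w_p)
    data.frame(
      S_p = a$S_p, d_c = a$d_c, w_p = a$w_p, ratio = a$ratio,
      regime_channel = ch, regime_slit = sl,
      ratio_dG_dG = partition_ratio("degennes", "degennes", a$d_c, a$w_p),
      ratio_dG_odijk = partition_ratio("degennes", "odijk", a$d_c, a$w_p,
                                       P = P, w = w),
      ratio_odijk_odijk = partition_ratio("odijk", "odijk", a$d_c, a$w_p))
  }))
  rownames(df) <- NULL
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
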