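#' Normalize an 8-ligand CICADA response profile
#'
#' For a cell that responded to at least one CICADA ligand, the smallest of
#' the 8 response amplitudes is subtracted (making the minimum exactly 0)
#' and the result is divided by the cell's maximum response:
#' `(X - Xmin) / Xmax`. Note the divisor is `Xmax`, not `Xmax - Xmin`, so
#' the normalized maximum is `(Xmax - Xmin)/Xmax`, below 1 whenever the
#' minimum is positive; `normMode = "minmax"` selects the conventional
#' `(X - Xmin)/(Xmax - Xmin)` form for sensitivity analysis. For a cell
#' that responded to no ligand, dividing by its (tiny) maximum would only
#' amplify noise, so the profile is instead divided by the mean response
#' across all 8 ligands (floored at 1e-6), placing sub-threshold responses
#' in context.
#'
#' @param amplitudes numeric length 8, raw peak amplitudes for the ligands
#'   SP, OXT, GRP, Oxo., taltirelin, NMB, CCK, NKB.
#' @param anyResponder logical: did the cell pass the responder rule for
#'   at least one ligand (from [detectResponses()] calls)?
#' @param normMode `"paper"` (default) or `"minmax"`.
#' @return numeric length 8; an all-zero non-responder profile returns a
#'   zero vector with attribute `"degenerate" = TRUE`.
#' @examples
#' x <- c(2, rep(0, 7))
#' normalizeProfile(x, TRUE)          # 1 at the first ligand, 0 elsewhere
#' @export
normalizeProfile <- function(amplitudes, anyResponder,
                             normMode = c("paper", "minmax")) {
  normMode <- match.arg(normMode)
  stopifnot(length(amplitudes) == 8L)
  x <- as.numeric(amplitudes)
  if (anyResponder) {
    xmin <- min(x); xmax <- max(x)
    den <- if (normMode == "paper") xmax else (xmax - xmin)
    out <- (x - xmin) / den
  } else {
    m <- max(mean(x), 1e-6)
    out <- x / m
    if (all(x == 0)) attr(out, "degenerate") <- TRUE
  }
  names(out) <- names(amplitudes)
  out
}

#' Build normalized CICADA profiles for all cells
#'
#' Extracts per-cell peak amplitudes and responder calls for the 8 ligand
#' events from a response table and applies [normalizeProfile()].
#'
#' @param calls data.frame from [detectResponses()] (must contain the
#'   ligand events).
#' @param config a [CicadaConfig-class].
#' @return data.frame with `cell_id`, `any_responder`, raw amplitudes
#'   (`amp_<ligand>`) and normalized values (`norm_<ligand>`).
#' @export
cicadaProfiles <- function(calls, config = cicadaConfig()) {
  lig <- calls[calls$kind == "ligand", , drop = FALSE]
  if (nrow(lig) == 0L) stop("no ligand events in the response table")
  out <- do.call(rbind, lapply(split(lig, lig$cell_id), function(g) {
    amps <- stats::setNames(rep(0, 8L), .LIGAND_FAMILIES)
    resp <- stats::setNames(rep(FALSE, 8L), .LIGAND_FAMILIES)
    for (i in seq_len(nrow(g))) {
      f <- g$family[i]
      amps[f] <- max(amps[f], g$peak_amp[i], na.rm = TRUE)
      resp[f] <- resp[f] || g$responder[i]
    }
    nz <- normalizeProfile(amps, any(resp), config@normMode)
    df <- data.frame(cell_id = g$cell_id[1], any_responder = any(resp),
                     row.names = NULL)
    df[paste0("amp_", .LIGAND_FAMILIES)] <- as.list(amps)
    df[paste0("norm_", .LIGAND_FAMILIES)] <- as.list(nz)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Cluster normalized ligand profiles into putative cell types
#'
#' K-means (Euclidean, `nInit` random restarts keeping the best inertia,
#' fully seeded) on the cells x 8 matrix of normalized CICADA amplitudes.
#' Only ligand-responsive cells should be supplied. When per-cell depths
#' are given, cluster labels are renumbered by ascending median depth, so
#' label 1 is the most superficial population -- mirroring the Ex1..Ex7
#' naming convention along the dorso-ventral axis.
#'
#' @param profiles numeric matrix (cells x 8) of normalized amplitudes,
#'   with cell ids as rownames.
#' @param k number of clusters (default 7).
#' @param seed random seed.
#' @param nInit number of random restarts.
#' @param depths optional named numeric of per-cell depths (um below the
#'   surface) used for depth-ordered relabeling.
#' @return list with `labels` (named integer), `centers`, `inertia`
#'   (total within-cluster sum of squares), `sizes`.
#' @export
clusterProfiles <- function(profiles, k = 7, seed = 1, nInit = 25,
                            depths = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k < 1 || k > n)
    stop("configuration error: k must lie in [1, number of cells]")
  if (k == 1) {
    labels <- stats::setNames(rep(1L, n), rownames(profiles))
    return(list(labels = labels, centers = matrix(colMeans(profiles), 1),
                inertia = sum(scale(profiles, scale = FALSE)^2), sizes = n))
  }
  set.seed(seed)
  km <- stats::kmeans(profiles, centers = k, nstart = nInit, iter.max = 100)
  labels <- km$cluster
  if (!is.null(depths)) {
    dep <- depths[rownames(profiles)]
    medd <- vapply(seq_len(k), function(cl)
      stats::median(dep[labels == cl], na.rm = TRUE), numeric(1))
    remap <- match(seq_len(k), order(medd))
    labels <- remap[labels]
    km$centers <- km$centers[order(medd), , drop = FALSE]
  }
  names(labels) <- rownames(profiles)
  list(labels = labels, centers = km$centers, inertia = km$tot.withinss,
       sizes = tabulate(labels, k))
}

#' Choose the number of clusters by silhouette
#'
#' Runs [clusterProfiles()] over a range of k and returns the k with the
#' highest mean silhouette width. Provided because the cluster count is
#' otherwise a fixed choice; a warning is emitted when every candidate
#' silhouette is weak (< 0.25), indicating no real cluster structure.
#'
#' @param profiles cells x 8 normalized matrix.
#' @param kRange integer candidates (all in [2, n-1]).
#' @param seed random seed.
#' @param nInit restarts per k.
#' @return list with `k` and `table` (k, mean silhouette width, inertia).
#' @export
selectK <- function(profiles, kRange = 2:10, seed = 1, nInit = 25) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) stop("configuration error: kRange must lie in [2, n-1]")
  dmat <- stats::dist(profiles)
  if (max(dmat) == 0)
    stop("selection error: all profiles are identical")
  tab <- do.call(rbind, lapply(kRange, function(k) {
    cl <- clusterProfiles(profiles, k = k, seed = seed, nInit = nInit)
    sil <- cluster::silhouette(as.integer(cl$labels), dmat)
    data.frame(k = k, silhouette = mean(sil[, "sil_width"]),
               inertia = cl$inertia)
  }))
  if (all(tab$silhouette < 0.25))
    warning("weak cluster structure: all silhouette widths < 0.25")
  list(k = tab$k[which.max(tab$silhouette)], table = tab)
}

#' Per-cluster summary report
#'
#' For each cluster: the population-average normalized ligand vector (the
#' radar-chart spokes), the depth distribution (median and IQR), the
#' relative abundance as a percentage of clustered cells, and optionally
#' the percent of member cells responding to each stimulus family.
#'
#' @param labels named integer cluster labels.
#' @param profiles cells x 8 normalized matrix (rownames = cell ids).
#' @param depths optional named numeric depths (um).
#' @param famResp optional family-response table ([assignFamilyResponse()]),
#'   pre block, used for per-family responder percentages.
#' @return data.frame, one row per cluster label 1..max(labels); empty
#'   clusters appear with zero abundance.
#' @export
clusterSummary <- function(labels, profiles, depths = NULL, famResp = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles)))
    colnames(profiles) <- paste0("L", seq_len(ncol(profiles)))
  k <- max(labels)
  nTot <- length(labels)
  rows <- lapply(seq_len(k), function(cl) {
    ids <- names(labels)[labels == cl]
    row <- data.frame(cluster = cl, n = length(ids),
                      abundance_pct = 100 * length(ids) / nTot)
    mp <- if (length(ids)) colMeans(profiles[ids, , drop = FALSE]) else
      rep(NA_real_, ncol(profiles))
    row[paste0("mean_", colnames(profiles))] <- as.list(mp)
    if (!is.null(depths)) {
      d <- depths[ids]
      row$depth_median <- if (length(d)) stats::median(d, na.rm = TRUE) else NA_real_
      row$depth_iqr <- if (length(d)) stats::IQR(d, na.rm = TRUE) else NA_real_
    }
    if (!is.null(famResp) && length(ids)) {
      fr <- famResp[famResp$cell_id %in% ids & famResp$block == "pre", ]
      for (fam in sort(unique(fr$family)))
        row[[paste0("pct_resp_", fam)]] <-
          100 * mean(fr$responder[fr$family == fam])
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    r[miss] <- NA
    r[unique(unlist(lapply(rows, names)))]
  }))
  rownames(out) <- NULL
  out
}
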