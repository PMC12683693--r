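# Linkage-map construction from pairwise two-point data: marker/individual
# filtering, duplicate binning, LOD-ladder clustering into linkage groups,
# homologue (phase-cluster) assignment, and weighted 1-D marker ordering
# with iterative elimination of ill-fitting markers.

#' Filter a dosage matrix and bin duplicate markers
#'
#' Removes markers and individuals whose missingness exceeds the given
#' thresholds, merges duplicate F1 individuals (dosage identity over shared
#' non-missing calls at or above `duplicate_indiv_threshold`; conflicting
#' calls in a merged pair become missing), masks dosage calls that are
#' impossible under a marker's segregation type (miscall artefacts), and
#' bins markers with identical dosage vectors, retaining one representative
#' per bin. Binned markers are restored at their representative's position
#' by [restore_bins()].
#'
#' @param x A `dosage_matrix`.
#' @param marker_missing_max Maximum fraction of missing calls per marker.
#' @param indiv_missing_max Maximum fraction of missing calls per individual.
#' @param duplicate_indiv_threshold Identity fraction at or above which two
#'   individuals are considered duplicates (default 0.98).
#' @param mask_impossible Mask calls impossible under the marker's
#'   segregation type (e.g. dosage 3 at a 1x0 marker) to missing before
#'   filtering (default TRUE).
#' @return list with `matrix` (filtered `dosage_matrix`), `bins` (named list
#'   mapping representative to member markers), `removed_markers`,
#'   `removed_individuals`, `merged_individuals`.
#' @export
filter_and_bin <- function(x, marker_missing_max = 0.1,
                           indiv_missing_max = 0.1,
                           duplicate_indiv_threshold = 0.98,
                           mask_impossible = TRUE) {
  stopifnot(inherits(x, "dosage_matrix"))
  .assert_prob(marker_missing_max, "marker_missing_max")
  .assert_prob(indiv_missing_max, "indiv_missing_max")
  .assert_prob(duplicate_indiv_threshold, "duplicate_indiv_threshold")
  X <- unclass(x)
  dm <- attr(x, "dosage_m"); dp <- attr(x, "dosage_p")

  if (mask_impossible) {
    for (i in seq_len(nrow(X))) {
      ok <- .possible_dosages(dm[i], dp[i])
      bad <- !is.na(X[i, ]) & !(X[i, ] %in% ok)
      X[i, bad] <- NA_integer_
    }
  }

  ## duplicate individuals
  merged <- list()
  n_ind <- ncol(X)
  if (n_ind > 1L) {
    drop_ind <- logical(n_ind)
    for (i in seq_len(n_ind - 1L)) {
      if (drop_ind[i]) next
      for (j in seq.int(i + 1L, n_ind)) {
        if (drop_ind[j]) next
        shared <- !is.na(X[, i]) & !is.na(X[, j])
        if (!any(shared)) next
        ident <- mean(X[shared, i] == X[shared, j])
        if (ident >= duplicate_indiv_threshold) {
          cons <- X[, i]
          fill <- is.na(cons) & !is.na(X[, j])
          cons[fill] <- X[fill, j]
          conflict <- shared & X[, i] != X[, j]
          cons[conflict] <- NA_integer_
          X[, i] <- cons
          drop_ind[j] <- TRUE
          merged[[length(merged) + 1L]] <-
            c(kept = colnames(X)[i], dropped = colnames(X)[j])
        }
      }
    }
    removed_dup <- colnames(X)[drop_ind]
    X <- X[, !drop_ind, drop = FALSE]
  } else {
    removed_dup <- character(0)
  }

  ## missingness filters: markers first, then individuals
  mk_miss <- rowMeans(is.na(X))
  bad_mk <- is.nan(mk_miss) | mk_miss > marker_missing_max
  removed_markers <- rownames(X)[bad_mk]
  X <- X[!bad_mk, , drop = FALSE]
  if (nrow(X) == 0L) {
    stop("all markers removed by filtering", call. = FALSE)
  }
  ind_miss <- colMeans(is.na(X))
  bad_ind <- is.nan(ind_miss) | ind_miss > indiv_missing_max
  removed_individuals <- colnames(X)[bad_ind]
  X <- X[, !bad_ind, drop = FALSE]
  if (ncol(X) == 0L) {
    stop("all individuals removed by filtering", call. = FALSE)
  }

  ## duplicate-marker binning: exact dosage-vector + parental-dosage identity
  sig <- paste(dm[rownames(X)], dp[rownames(X)],
               apply(X, 1L, paste, collapse = ","), sep = "|")
  first <- !duplicated(sig)
  reps <- rownames(X)[first]
  bins <- split(rownames(X), match(sig, sig[first]))
  names(bins) <- reps
  Xr <- X[first, , drop = FALSE]

  mk <- attr(x, "markers")
  if (!is.null(mk)) mk <- mk[mk$marker %in% rownames(Xr)]
  out <- structure(Xr,
                   dosage_m = dm[rownames(Xr)], dosage_p = dp[rownames(Xr)],
                   markers = mk,
                   class = c("dosage_matrix", "matrix", "array"))
  list(matrix = out, bins = bins,
       removed_markers = removed_markers,
       removed_individuals = c(removed_dup, removed_individuals),
       merged_individuals = merged)
}

# Offspring dosages possible for a marker under the bivalent model
# (plus DR, which can raise a simplex gamete contribution to 2).
.possible_dosages <- function(dm, dp) {
  gm <- 0:2; gm <- gm[gm <= dm & gm >= dm - 2L]
  gp <- 0:2; gp <- gp[gp <= dp & gp >= dp - 2L]
  sort(unique(as.vector(outer(gm, gp, `+`))))
}

#' Cluster markers into linkage groups along a LOD ladder
#'
#' Builds the graph whose edges connect marker pairs with `LOD >=`
#' threshold and raises the threshold along `lod_ladder` until at least
#' `n_groups` connected components (of two or more markers) emerge; the
#' `n_groups` largest components become the linkage groups and everything
#' else is flagged unassigned.
#'
#' @param pairwise data.table from [estimate_two_point_batch()] (columns
#'   `marker1`, `marker2`, `LOD`).
#' @param n_groups Expected number of linkage groups (default 8).
#' @param lod_ladder Increasing LOD thresholds to try (default
#'   `c(3, 4, 5, 6, 7, 10)`).
#' @return list with `groups` (named integer vector: marker -> group 1..),
#'   `unassigned` (character), `lod_used`.
#' @export
cluster_linkage_groups <- function(pairwise, n_groups = 8,
                                   lod_ladder = c(3, 4, 5, 6, 7, 10)) {
  markers <- unique(c(pairwise$marker1, pairwise$marker2))
  for (thr in sort(lod_ladder)) {
    keep <- pairwise$LOD >= thr & !is.na(pairwise$r)
    comp <- .components(markers, pairwise$marker1[keep], pairwise$marker2[keep])
    sizes <- table(comp)
    big <- names(sizes)[sizes >= 2L]
    if (length(big) >= n_groups) {
      ord <- big[order(-sizes[big])]
      chosen <- ord[seq_len(n_groups)]
      groups <- stats::setNames(match(comp, chosen), markers)
      unassigned <- markers[is.na(groups)]
      groups <- groups[!is.na(groups)]
      return(list(groups = groups, unassigned = unassigned, lod_used = thr))
    }
  }
  stop(sprintf(
    "could not separate %d linkage groups at max LOD %.1f (achieved %d)",
    n_groups, max(lod_ladder), length(big)), call. = FALSE)
}

# Connected components via union-find; returns component id per node.
.components <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fi <- idx[from]; ti <- idx[to]
  for (k in seq_along(fi)) {
    a <- find(fi[k]); b <- find(ti[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_along(nodes), find, integer(1))
}

#' Assign linkage-group markers to homologues
#'
#' Within one linkage group, markers simplex in a parent are partitioned
#' into at most four coupling-phase clusters per parent (edges where the
#' estimated phase is coupling and `LOD >=` threshold, threshold raised
#' along the ladder while more than four clusters remain). Maternal and
#' paternal homologues are matched through markers simplex in both parents
#' (1x1); all other segregating markers are then placed on the homologue(s)
#' with the strongest total coupling LOD.
#'
#' @param x The `dosage_matrix` (need not be restricted to the group;
#'   parental dosages are read from its attributes).
#' @param group_markers Markers of one linkage group.
#' @param pairwise data.table from [estimate_two_point_batch()] covering the
#'   group's pairs.
#' @param lod_ladder LOD thresholds (default `c(3, 4, 5, 6, 7, 10)`).
#' @return list with `maternal` and `paternal` (named homologue index 1..4
#'   per simplex marker), `bridge` (homologue correspondence matrix from
#'   1x1 markers, or NULL with a message when no 1x1 markers exist) and
#'   `other` (data.table: marker, parent, homologue for non-simplex types).
#' @export
assign_homologues <- function(x, group_markers, pairwise,
                              lod_ladder = c(3, 4, 5, 6, 7, 10)) {
  stopifnot(inherits(x, "dosage_matrix"))
  dm <- attr(x, "dosage_m"); dp <- attr(x, "dosage_p")
  pw <- pairwise[pairwise$marker1 %in% group_markers &
                 pairwise$marker2 %in% group_markers, ]

  cluster_parent <- function(simplex, phase_col) {
    if (length(simplex) == 0L) return(stats::setNames(integer(0), character(0)))
    sub <- pw[pw$marker1 %in% simplex & pw$marker2 %in% simplex &
              !is.na(pw$r) & pw[[phase_col]] == "coupling", ]
    for (thr in sort(lod_ladder)) {
      keep <- sub$LOD >= thr
      comp <- .components(simplex, sub$marker1[keep], sub$marker2[keep])
      sizes <- table(comp)
      big <- as.integer(names(sizes)[sizes >= 2L])
      if (length(big) > 4L) next
      ## at most 4 non-trivial coupling clusters: these are the homologues;
      ## weakly attached leftovers join the cluster with the best summed
      ## coupling LOD (NA when unconnected)
      if (length(big) == 0L) big <- as.integer(names(sizes))[1L]
      hom <- stats::setNames(match(comp, big), simplex)
      left <- simplex[is.na(hom)]
      for (mk_l in left) {
        e <- sub[(sub$marker1 == mk_l | sub$marker2 == mk_l), ]
        oth <- ifelse(e$marker1 == mk_l, e$marker2, e$marker1)
        ok2 <- !is.na(hom[oth])
        if (!any(ok2)) next
        sc <- tapply(e$LOD[ok2], hom[oth[ok2]], sum)
        hom[mk_l] <- as.integer(names(sc)[which.max(sc)])
      }
      return(hom)
    }
    stop(sprintf(
      "phase inconsistency: more than 4 coupling clusters at max LOD in %s",
      phase_col), call. = FALSE)
  }

  simplex_m <- group_markers[dm[group_markers] == 1L & dp[group_markers] == 0L]
  simplex_p <- group_markers[dm[group_markers] == 0L & dp[group_markers] == 1L]
  bridge_mk <- group_markers[dm[group_markers] == 1L & dp[group_markers] == 1L]

  hm <- cluster_parent(simplex_m, "phase_m")
  hp <- cluster_parent(simplex_p, "phase_p")

  ## cross-parent matching through 1x1 markers
  bridge <- NULL
  if (length(bridge_mk) > 0L && length(hm) && length(hp)) {
    bridge <- matrix(0, 4L, 4L,
                     dimnames = list(maternal = 1:4, paternal = 1:4))
    for (b in bridge_mk) {
      e <- pw[(pw$marker1 == b | pw$marker2 == b) & !is.na(pw$r), ]
      other <- ifelse(e$marker1 == b, e$marker2, e$marker1)
      em <- e$phase_m == "coupling" & other %in% names(hm)
      ep <- e$phase_p == "coupling" & other %in% names(hp)
      if (any(em) && any(ep)) {
        i <- hm[other[em][which.max(e$LOD[em])]]
        j <- hp[other[ep][which.max(e$LOD[ep])]]
        bridge[i, j] <- bridge[i, j] + 1
      }
    }
  }

  ## remaining segregating markers: best total coupling LOD per homologue
  placed <- c(names(hm), names(hp))
  rest <- setdiff(group_markers[(dm[group_markers] %in% 1:3) |
                                (dp[group_markers] %in% 1:3)], placed)
  other_rows <- list()
  place_on <- function(mk, hset, phase_col) {
    e <- pw[(pw$marker1 == mk | pw$marker2 == mk) & !is.na(pw$r), ]
    oth <- ifelse(e$marker1 == mk, e$marker2, e$marker1)
    sel <- e[[phase_col]] %in% c("coupling", "mixed") & oth %in% names(hset)
    if (!any(sel)) return(NA_integer_)
    sc <- tapply(e$LOD[sel], hset[oth[sel]], sum)
    as.integer(names(sc)[which.max(sc)])
  }
  for (mk in rest) {
    if (dm[mk] %in% 1:3 && length(hm)) {
      other_rows[[length(other_rows) + 1L]] <- data.table::data.table(
        marker = mk, parent = "maternal",
        homologue = place_on(mk, hm, "phase_m"))
    }
    if (dp[mk] %in% 1:3 && length(hp)) {
      other_rows[[length(other_rows) + 1L]] <- data.table::data.table(
        marker = mk, parent = "paternal",
        homologue = place_on(mk, hp, "phase_p"))
    }
  }
  other <- if (length(other_rows)) data.table::rbindlist(other_rows) else
    data.table::data.table(marker = character(0), parent = character(0),
                           homologue = integer(0))
  if (is.null(bridge)) {
    message("cross-parent homologue matching undetermined (no 1x1 markers)")
  }
  list(maternal = hm, paternal = hp, bridge = bridge, other = other)
}

# Weighted stress of a 1-D configuration against target distances.
.stress <- function(x, D, W) {
  delta <- abs(outer(x, x, `-`))
  sum(W * (delta - D)^2) / 2
}

# One-dimensional weighted SMACOF (Guttman transform) for |x_i - x_j| ~ d_ij.
# Vp (the pseudo-inverse factor) can be precomputed by the caller.
.smacof1d <- function(x, D, W, iters = 60, tol = 1e-8, Vp = NULL) {
  n <- length(x)
  if (is.null(Vp)) {
    V <- -W
    diag(V) <- rowSums(W)
    Vp <- solve(V + 1 / n, tol = 1e-30)  # (V + 11'/n)^-1; p-inverse trick
  }
  s_old <- .stress(x, D, W)
  for (it in seq_len(iters)) {
    delta <- abs(outer(x, x, `-`))
    Bm <- ifelse(delta > 1e-12, -W * D / pmax(delta, 1e-12), 0)
    diag(Bm) <- 0
    diag(Bm) <- -rowSums(Bm)
    x <- as.vector(Vp %*% (Bm %*% x))
    s_new <- .stress(x, D, W)
    if (s_old - s_new < tol * max(s_old, 1e-12)) break
    s_old <- s_new
  }
  x
}

# Per-marker nearest-neighbour stress in the fitted order.
.marker_stress <- function(x, D, W, k = 2) {
  ord <- order(x)
  n <- length(x)
  s <- numeric(n)
  for (ii in seq_len(n)) {
    pos <- which(ord == ii)
    span <- setdiff(seq(max(1L, pos - k), min(n, pos + k)), pos)
    nb <- ord[span]
    w <- W[ii, nb]
    if (sum(w) == 0) { s[ii] <- 0; next }
    s[ii] <- sum(w * (abs(x[ii] - x[nb]) - D[ii, nb])^2) / sum(w)
  }
  s
}

#' Order the markers of one linkage group
#'
#' Pairwise recombination fractions are converted to Haldane map distances
#' `d = -50 ln(1 - 2r)` and embedded on a line by weighted least squares
#' (weights `LOD^2`): spectral seriation (Fiedler vector of the weighted
#' Laplacian) provides the initial configuration, a 1-D weighted SMACOF
#' majorisation minimises the stress `sum w_ij (|x_i - x_j| - d_ij)^2`, and
#' adjacent swaps are applied until no further stress decrease. Markers
#' whose nearest-neighbour stress exceeds `stress_multiple` times the group
#' median are then removed one at a time (worst first, re-fitting after
#' each removal). Positions are shifted so the smallest is 0.
#'
#' @param pairwise data.table of two-point results for the group's pairs.
#' @param group_markers Markers to order (>= 2).
#' @param stress_multiple Ill-fit elimination threshold as a multiple of the
#'   median marker stress (default 3).
#' @param max_drop_frac Maximum fraction of markers removable as ill-fitting
#'   (default 0.2).
#' @param min_drop_cM Absolute floor: a marker is only dropped when its
#'   root-mean-square nearest-neighbour residual also exceeds this many cM
#'   (default 5, several times the adjacent-distance noise at n ~ 200).
#'   Prevents pruning sub-resolution wobble when the group median stress is
#'   near zero.
#' @param init_positions Optional named vector of starting positions (cM);
#'   when supplied the embedding is polished from it instead of the
#'   spectral multistart (used when re-ordering merged maps, keeping the
#'   consensus stable where the data cannot distinguish orders).
#' @return list with `map` (data.table: marker, position_cM in input-marker
#'   order of the fit), `dropped` (ill-fitting markers removed) and
#'   `stress`.
#' @export
order_markers <- function(pairwise, group_markers, stress_multiple = 3,
                          max_drop_frac = 0.2, min_drop_cM = 5,
                          init_positions = NULL) {
  mk <- sort(unique(group_markers))   # canonical order: result does not
  n <- length(mk)                     # depend on the caller's marker order
  if (n < 2L) stop("need >= 2 markers to order", call. = FALSE)
  pw <- pairwise[pairwise$marker1 %in% mk & pairwise$marker2 %in% mk &
                 !is.na(pairwise$r), ]
  i <- match(pw$marker1, mk); j <- match(pw$marker2, mk)
  D <- matrix(0, n, n); W <- matrix(0, n, n)
  d <- haldane_cM(pmin(pw$r, 0.499))
  w <- pw$LOD^2
  D[cbind(i, j)] <- d; D[cbind(j, i)] <- d
  W[cbind(i, j)] <- w; W[cbind(j, i)] <- w

  comp <- .components(mk, pw$marker1[pw$LOD > 0], pw$marker2[pw$LOD > 0])
  if (length(unique(comp)) > 1L) {
    sizes <- table(comp)
    stop(sprintf("pairwise graph disconnected: components of sizes %s",
                 paste(sizes, collapse = ", ")), call. = FALSE)
  }

  fit_positions <- function(keep, n_starts = 3L, x_init = NULL,
                            rounds = 8L) {
    Dk <- D[keep, keep, drop = FALSE]
    Wk <- W[keep, keep, drop = FALSE]
    nk <- sum(keep)
    if (nk == 2L) {
      return(c(0, Dk[1L, 2L]))
    }
    Vsm <- -Wk
    diag(Vsm) <- rowSums(Wk)
    Vp <- solve(Vsm + 1 / nk, tol = 1e-30)
    nbr <- lapply(seq_len(nk), function(ii) which(Wk[ii, ] > 0))
    top_nbr <- lapply(seq_len(nk), function(ii) {
      nb <- nbr[[ii]]
      nb[order(-Wk[ii, nb])][seq_len(min(40L, length(nb)))]
    })
    ## one cycle of local improvement: single-marker repositioning (each
    ## marker moved to the 1-D point minimising its own stress among the
    ## piecewise-quadratic breakpoints x_j +/- d_ij), then adjacent swaps.
    reposition <- function(x) {
      for (ii in seq_len(nk)) {
        nb <- nbr[[ii]]
        if (!length(nb)) next
        top <- top_nbr[[ii]]
        cand <- unique(c(x[top] - Dk[ii, top], x[top] + Dk[ii, top], x[ii]))
        resid <- abs(outer(cand, x[nb], `-`)) -
          matrix(Dk[ii, nb], length(cand), length(nb), byrow = TRUE)
        sc <- as.vector((resid * resid) %*% Wk[ii, nb])
        x[ii] <- cand[which.min(sc)]
      }
      x
    }
    row_stress <- function(i, xv) {
      sum(Wk[i, ] * (abs(xv[i] - xv) - Dk[i, ])^2)
    }
    swaps <- function(x) {
      for (pass in 1:20) {
        improved <- FALSE
        ord <- order(x)
        for (t in seq_len(nk - 1L)) {
          a <- ord[t]; b <- ord[t + 1L]
          xs <- x; xs[c(a, b)] <- xs[c(b, a)]
          del <- (row_stress(a, xs) + row_stress(b, xs)) -
            (row_stress(a, x) + row_stress(b, x))
          if (del < -1e-9) {
            x <- xs
            improved <- TRUE
          }
        }
        if (!improved) break
      }
      x
    }
    ## block reversals (2-opt) unfold segments that single swaps cannot:
    ## a window of the current order is mirrored in place and kept when the
    ## total stress decreases
    revblocks <- function(x) {
      coarse <- unique(pmax(c(nk %/% 2, nk %/% 3, nk %/% 5, nk %/% 8), 3L))
      fine <- seq(3L, min(10L, nk))
      widths <- c(coarse, fine)
      strides <- c(pmax(1L, coarse %/% 2L), rep(1L, length(fine)))
      for (wi in seq_along(widths)) {
        w <- widths[wi]
        if (w > nk) next
        ord <- order(x)
        for (s0 in seq(1L, nk - w + 1L, by = strides[wi])) {
          blk <- ord[s0:(s0 + w - 1L)]
          a <- min(x[blk]); b <- max(x[blk])
          xb <- a + b - x[blk]
          ## within-block distances are mirror-invariant: only block-vs-rest
          ## terms change
          rest <- ord[-(s0:(s0 + w - 1L))]
          Wc <- Wk[blk, rest, drop = FALSE]
          Dc <- Dk[blk, rest, drop = FALSE]
          del_old <- abs(outer(x[blk], x[rest], `-`)) - Dc
          del_new <- abs(outer(xb, x[rest], `-`)) - Dc
          if (sum(Wc * (del_new * del_new - del_old * del_old)) < -1e-9) {
            x[blk] <- xb
            ord <- order(x)
          }
        }
      }
      x
    }
    polish <- function(x, n_rounds = rounds) {
      s_old <- Inf
      for (round in seq_len(n_rounds)) {
        x <- .smacof1d(x, Dk, Wk, iters = 30, Vp = Vp)
        x <- reposition(x)
        x <- revblocks(x)
        x <- swaps(x)
        s <- .stress(x, Dk, Wk)
        if (s_old - s < 1e-6 * max(s_old, 1e-12)) break
        s_old <- s
      }
      x <- .smacof1d(x, Dk, Wk, iters = 30, Vp = Vp)
      list(x = x, s = .stress(x, Dk, Wk))
    }
    if (!is.null(x_init)) {
      ## warm start (used when refitting after an ill-fit removal)
      return(polish(x_init, n_rounds = rounds)$x)
    }
    ## spectral seriation starts: Fiedler vectors of the plain and the
    ## normalised weighted Laplacian (the plain one can isolate weakly
    ## connected markers; the normalised one is robust to degree spread),
    ## plus the next normalised eigenvector; best final stress wins
    deg <- rowSums(Wk)
    L <- -Wk; diag(L) <- deg
    ev <- eigen(L, symmetric = TRUE)
    dm <- 1 / sqrt(pmax(deg, 1e-12))
    Ln <- diag(nk) - (dm * Wk) %*% diag(dm)
    evn <- eigen(Ln, symmetric = TRUE)
    rescale <- function(v) {
      v * (sum(Wk * Dk) / max(sum(Wk * abs(outer(v, v, `-`))), 1e-9))
    }
    starts <- list(rescale(ev$vectors[, nk - 1L]),
                   rescale(evn$vectors[, nk - 1L] * dm),
                   rescale(evn$vectors[, nk - 2L] * dm))
    best <- NULL
    for (s in seq_len(min(n_starts, length(starts)))) {
      r <- polish(starts[[s]])
      if (is.null(best) || r$s < best$s) best <- r
    }
    best$x
  }

  keep <- rep(TRUE, n)
  if (!is.null(init_positions) && all(mk %in% names(init_positions))) {
    x <- fit_positions(keep, x_init = unname(init_positions[mk]))
  } else {
    x <- fit_positions(keep)
  }
  dropped <- character(0)
  max_drop <- floor(max_drop_frac * n)
  while (sum(keep) > 2L && length(dropped) < max_drop) {
    xk <- x
    Dk <- D[keep, keep, drop = FALSE]
    Wk <- W[keep, keep, drop = FALSE]
    s <- .marker_stress(xk, Dk, Wk)
    ## marker stress is a weight-normalised mean squared residual (cM^2),
    ## so the absolute floor compares in map units
    rms <- sqrt(s)
    med <- stats::median(s)
    eligible <- s > stress_multiple * med & rms > min_drop_cM
    if (med <= 0 || !any(eligible)) break
    s[!eligible] <- -Inf
    worst_local <- which.max(s)
    worst <- which(keep)[worst_local]
    keep[worst] <- FALSE
    dropped <- c(dropped, mk[worst])
    x <- fit_positions(keep, x_init = x[-worst_local], rounds = 3L)
  }
  if (length(dropped)) {
    ## removals reshape the stress landscape: polish to convergence
    x <- fit_positions(keep, x_init = x, rounds = 10L)
  }

  pos <- x - min(x)
  map <- data.table::data.table(marker = mk[keep], position_cM = pos)
  data.table::setorder(map, position_cM)
  list(map = map, dropped = dropped,
       stress = .stress(x, D[keep, keep, drop = FALSE],
                        W[keep, keep, drop = FALSE]))
}

#' Restore binned markers into a map
#'
#' Binned duplicates re-enter at the position of their bin representative;
#' representative positions are unchanged.
#'
#' @param map data.table with `marker`, `linkage_group`, `position_cM`.
#' @param bins Named list from [filter_and_bin()].
#' @return Extended map data.table, sorted by group and position.
#' @export
restore_bins <- function(map, bins) {
  map <- data.table::copy(data.table::as.data.table(map))
  extra <- list()
  for (rep_mk in intersect(names(bins), map$marker)) {
    members <- setdiff(bins[[rep_mk]], rep_mk)
    if (!length(members)) next
    row <- map[map$marker == rep_mk, ]
    add <- row[rep(1L, length(members)), ]
    add$marker <- members
    add$bin_representative <- rep_mk
    extra[[length(extra) + 1L]] <- add
  }
  map$bin_representative <- map$marker
  if (length(extra)) {
    map <- data.table::rbindlist(c(list(map), extra), use.names = TRUE)
  }
  if ("linkage_group" %in% names(map)) {
    data.table::setorder(map, linkage_group, position_cM)
  } else {
    data.table::setorder(map, position_cM)
  }
  map
}

#' Build a genetic map for one population
#'
#' Convenience pipeline: [filter_and_bin()], batch two-point estimation,
#' [cluster_linkage_groups()] on simplex x nulliplex markers, within-group
#' two-point estimation over all retained markers, [order_markers()] per
#' group and [restore_bins()].
#'
#' @param x A `dosage_matrix`.
#' @param n_groups Expected number of linkage groups.
#' @param lod_ladder LOD thresholds for clustering.
#' @param marker_missing_max,indiv_missing_max,duplicate_indiv_threshold
#'   Passed to [filter_and_bin()].
#' @param stress_multiple Passed to [order_markers()].
#' @return list of class `genetic_map_build`: `map` (data.table marker,
#'   linkage_group, position_cM, bin_representative), `pairwise` (per-group
#'   two-point results), `groups`, `bins`, `dropped`, `filter`.
#' @export
build_map <- function(x, n_groups = 8, lod_ladder = c(3, 4, 5, 6, 7, 10),
                      marker_missing_max = 0.1, indiv_missing_max = 0.1,
                      duplicate_indiv_threshold = 0.98,
                      stress_multiple = 3) {
  fb <- filter_and_bin(x, marker_missing_max, indiv_missing_max,
                       duplicate_indiv_threshold)
  X <- fb$matrix
  dm <- attr(X, "dosage_m"); dp <- attr(X, "dosage_p")
  mks <- rownames(X)

  ## clustering on markers simplex in either parent
  simplex <- mks[(dm == 1L & dp == 0L) | (dm == 0L & dp == 1L)]
  sm <- mks[dm == 1L & dp == 0L]
  sp <- mks[dm == 0L & dp == 1L]
  bridge <- mks[dm == 1L & dp == 1L]
  cl_set <- c(sm, sp, bridge)
  prs <- t(utils::combn(cl_set, 2L))
  ## drop 1x0 x 0x1 pairs: no parent segregates for both, no linkage signal
  useless <- (prs[, 1L] %in% sm & prs[, 2L] %in% sp) |
             (prs[, 1L] %in% sp & prs[, 2L] %in% sm)
  prs <- prs[!useless, , drop = FALSE]
  pw_cl <- estimate_two_point_batch(X, prs)
  cl <- cluster_linkage_groups(pw_cl, n_groups = n_groups,
                               lod_ladder = lod_ladder)

  ## per-group ordering over all segregating markers assigned by linkage
  groups <- cl$groups
  rest <- setdiff(mks[(dm %in% 1:3) | (dp %in% 1:3)], names(groups))
  maps <- list()
  pairwise <- list()
  dropped <- character(0)
  for (g in sort(unique(groups))) {
    gm <- names(groups)[groups == g]
    ## attach unclustered marker types to this group by best LOD later;
    ## ordering itself runs on the group's markers plus attached ones
    maps[[g]] <- gm
  }
  ## attach remaining seg types to groups via strongest linkage
  if (length(rest)) {
    anchor <- names(groups)
    prs2 <- cbind(rep(rest, each = 0L), character(0))
    ## sample up to 30 anchors per group for attachment
    anchors <- unlist(lapply(sort(unique(groups)), function(g) {
      gm <- names(groups)[groups == g]
      utils::head(gm, 30L)
    }))
    prs2 <- as.matrix(expand.grid(rest, anchors, stringsAsFactors = FALSE))
    pw2 <- estimate_two_point_batch(X, prs2)
    pw2$g <- groups[pw2$marker2]
    agg <- pw2[!is.na(pw2$r), list(score = sum(LOD)), by = c("marker1", "g")]
    if (nrow(agg)) {
      best <- agg[agg[, .I[which.max(score)], by = "marker1"]$V1]
      strong <- best[best$score >= min(lod_ladder)]
      for (k in seq_len(nrow(strong))) {
        g <- strong$g[k]
        maps[[g]] <- c(maps[[g]], strong$marker1[k])
      }
    }
  }

  map_rows <- list()
  for (g in sort(unique(groups))) {
    gm <- maps[[g]]
    prs3 <- t(utils::combn(gm, 2L))
    pw3 <- estimate_two_point_batch(X, prs3)
    om <- order_markers(pw3, gm, stress_multiple = stress_multiple)
    dropped <- c(dropped, om$dropped)
    mp <- om$map
    mp$linkage_group <- g
    ## per-parent homologue labels (NA where assignment is undetermined)
    hm <- rep(NA_integer_, nrow(mp))
    hp <- rep(NA_integer_, nrow(mp))
    ha <- tryCatch(suppressMessages(assign_homologues(X, gm, pw3,
                                                      lod_ladder = lod_ladder)),
                   error = function(e) NULL)
    if (!is.null(ha)) {
      hm <- unname(ha$maternal[mp$marker])
      hp <- unname(ha$paternal[mp$marker])
      oth <- ha$other
      for (k in seq_len(nrow(oth))) {
        i <- match(oth$marker[k], mp$marker)
        if (is.na(i)) next
        if (oth$parent[k] == "maternal") {
          hm[i] <- oth$homologue[k]
        } else {
          hp[i] <- oth$homologue[k]
        }
      }
    }
    mp$homologue_maternal <- hm
    mp$homologue_paternal <- hp
    map_rows[[g]] <- mp
    pairwise[[g]] <- pw3
  }
  map <- data.table::rbindlist(map_rows)
  map <- restore_bins(map, fb$bins)
  structure(list(map = map, pairwise = pairwise, groups = groups,
                 unassigned = cl$unassigned, bins = fb$bins,
                 dropped = dropped, filter = fb[-(1:2)]),
            class = "genetic_map_build")
}

#' @export
print.genetic_map_build <- function(x, ...) {
  tab <- x$map[, list(markers = .N, length_cM = max(position_cM)),
               by = "linkage_group"]
  cat("<genetic_map_build>\n")
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}
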