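# Two-point linkage estimation for autotetraploid F1 dosage data.
#
# Model: bivalent polysomic inheritance. Each parent's four homologues form
# one of the three bivalent pairings with equal probability; within a
# bivalent the transmitted chromatid carries the first homologue's allele at
# locus 1 with probability 1/2 and switches carrier between the two loci
# with probability r (the recombination fraction). The two-locus gamete
# distribution follows by exhaustive enumeration and is exactly quadratic in
# r; the offspring joint-dosage distribution (convolution over the two
# parents) is quartic. Likelihoods are therefore evaluated from precomputed
# polynomial coefficients.

#' Classify the segregation type of a marker
#'
#' @param maternal_dosage,paternal_dosage Integer allele dosages in 0..4.
#' @return An object of class `seg_type`: `label` (e.g. `"1x0"`),
#'   `maternal`, `paternal` and `informative` (FALSE when neither parent
#'   segregates, i.e. both dosages are 0 or 4).
#' @examples
#' classify_segregation(1, 0)  # simplex x nulliplex
#' classify_segregation(0, 0)$informative
#' @export
classify_segregation <- function(maternal_dosage, paternal_dosage) {
  for (d in c(maternal_dosage, paternal_dosage)) {
    if (!is.numeric(d) || length(d) != 1L || is.na(d) ||
        d != round(d) || d < 0 || d > 4) {
      stop("dosages must be integers in 0..4", call. = FALSE)
    }
  }
  m <- as.integer(maternal_dosage)
  p <- as.integer(paternal_dosage)
  structure(list(
    label = sprintf("%dx%d", m, p),
    maternal = m, paternal = p,
    informative = (m %in% 1:3) || (p %in% 1:3)
  ), class = "seg_type")
}

#' @export
print.seg_type <- function(x, ...) {
  cat(sprintf("<seg_type %s%s>\n", x$label,
              if (x$informative) "" else " (uninformative)"))
  invisible(x)
}

#' Phase of a marker pair within one parent
#'
#' The phase of two markers with dosages `dosage1` and `dosage2` in one
#' tetraploid parent is summarised, up to homologue permutation, by the
#' number of homologues carrying both alleles (`overlap`). The maximal
#' possible overlap is coupling, the minimal is repulsion; intermediate
#' overlaps of multiplex pairs are mixed.
#'
#' @param dosage1,dosage2 Parental dosages (0..4) of the two markers.
#' @param overlap Number of shared carrier homologues.
#' @return Object of class `pair_phase` with `dosage1`, `dosage2`,
#'   `overlap` and `label` in `{"coupling", "repulsion", "mixed", "none"}`
#'   (`"none"` when the parent does not segregate for both markers).
#' @export
pair_phase <- function(dosage1, dosage2, overlap) {
  lo <- max(0L, dosage1 + dosage2 - 4L)
  hi <- min(dosage1, dosage2)
  if (overlap < lo || overlap > hi) {
    stop(sprintf("overlap %d impossible for dosages (%d, %d)",
                 overlap, dosage1, dosage2), call. = FALSE)
  }
  label <- if (!(dosage1 %in% 1:3) || !(dosage2 %in% 1:3)) {
    "none"
  } else if (overlap == hi && lo != hi) {
    "coupling"
  } else if (overlap == lo && lo != hi) {
    "repulsion"
  } else if (lo == hi) {
    "fixed"
  } else {
    "mixed"
  }
  structure(list(dosage1 = as.integer(dosage1), dosage2 = as.integer(dosage2),
                 overlap = as.integer(overlap), label = label),
            class = "pair_phase")
}

# Candidate overlaps for a dosage pair in one parent.
.overlap_range <- function(d1, d2) {
  seq.int(max(0L, d1 + d2 - 4L), min(d1, d2))
}

# Exact two-locus gamete-dosage distribution for one parent: enumeration of
# the 3 equiprobable bivalent pairings, chromatid choice and recombination.
# Returns a 3 x 3 matrix, rows = gamete dosage at locus 1 (0..2).
.gamete_table <- function(d1, d2, overlap, r) {
  A <- seq_len(d1)
  nonA <- setdiff(1:4, A)
  B <- c(A[seq_len(overlap)], nonA[seq_len(d2 - overlap)])
  h <- matrix(0L, 4L, 2L)
  h[A, 1L] <- 1L
  h[B, 2L] <- 1L
  P <- matrix(0, 3L, 3L)
  for (p in .PAIRINGS) {
    bd <- lapply(1:2, function(b) {
      i <- p[b, 1L]; j <- p[b, 2L]
      d <- matrix(0, 2L, 2L)
      d[h[i, 1L] + 1L, h[i, 2L] + 1L] <- d[h[i, 1L] + 1L, h[i, 2L] + 1L] + (1 - r) / 2
      d[h[j, 1L] + 1L, h[j, 2L] + 1L] <- d[h[j, 1L] + 1L, h[j, 2L] + 1L] + (1 - r) / 2
      d[h[i, 1L] + 1L, h[j, 2L] + 1L] <- d[h[i, 1L] + 1L, h[j, 2L] + 1L] + r / 2
      d[h[j, 1L] + 1L, h[i, 2L] + 1L] <- d[h[j, 1L] + 1L, h[i, 2L] + 1L] + r / 2
      d
    })
    for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1) {
      P[a1 + a2 + 1L, b1 + b2 + 1L] <- P[a1 + a2 + 1L, b1 + b2 + 1L] +
        bd[[1L]][a1 + 1L, b1 + 1L] * bd[[2L]][a2 + 1L, b2 + 1L] / 3
    }
  }
  dimnames(P) <- list(gamete1 = 0:2, gamete2 = 0:2)
  P
}

#' Joint two-locus gamete distribution under bivalent polysomic meiosis
#'
#' Probability table over gamete dosage classes (0..2 at each locus) for a
#' marker pair in one parent, computed by exhaustive enumeration of the
#' three equiprobable bivalent pairings, chromatid choice and recombination
#' events parameterised by `r`. Quadrivalents and double reduction are
#' outside this model (q = 0, alpha = 0).
#'
#' @param phase A [pair_phase()].
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return 3 x 3 probability matrix summing to 1.
#' @export
joint_gamete_distribution <- function(phase, r) {
  stopifnot(inherits(phase, "pair_phase"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    stop("r must lie in [0, 0.5]", call. = FALSE)
  }
  .gamete_table(phase$dosage1, phase$dosage2, phase$overlap, r)
}

# Quartic polynomial coefficients (25 x 5) of the offspring joint-dosage
# probabilities for one phase combination. Row order: dosage1 + 5*dosage2.
.offspring_coeffs <- function(dm1, dm2, om, dp1, dp2, op) {
  nodes <- c(0, 0.125, 0.25, 0.375, 0.5)
  V <- outer(nodes, 0:4, `^`)
  Vi <- solve(V)
  probs <- vapply(nodes, function(r) {
    gm <- .gamete_table(dm1, dm2, om, r)
    gp <- .gamete_table(dp1, dp2, op, r)
    off <- matrix(0, 5L, 5L)
    for (i in 0:2) for (j in 0:2) for (k in 0:2) for (l in 0:2) {
      off[i + k + 1L, j + l + 1L] <- off[i + k + 1L, j + l + 1L] +
        gm[i + 1L, j + 1L] * gp[k + 1L, l + 1L]
    }
    as.vector(off)
  }, numeric(25L))
  probs %*% t(Vi)   # 25 x 5: coefficient of r^0..r^4 per class
}

.coeff_cache <- new.env(parent = emptyenv())

.offspring_coeffs_cached <- function(dm1, dm2, om, dp1, dp2, op) {
  key <- paste(dm1, dm2, om, dp1, dp2, op, sep = "_")
  got <- .coeff_cache[[key]]
  if (is.null(got)) {
    got <- .offspring_coeffs(dm1, dm2, om, dp1, dp2, op)
    .coeff_cache[[key]] <- got
  }
  got
}

.class_probs <- function(coeffs, r) {
  p <- as.vector(coeffs %*% r^(0:4))
  pmax(p, 0)
}

# Enumerate candidate phase combinations for a seg-type pair, ordered
# coupling-first (larger overlaps first) so that likelihood ties break
# toward coupling.
.phase_combos <- function(dm1, dp1, dm2, dp2) {
  om <- rev(.overlap_range(dm1, dm2))
  op <- rev(.overlap_range(dp1, dp2))
  combos <- expand.grid(op = op, om = om)[, c("om", "op")]
  combos[order(-(combos$om + combos$op)), , drop = FALSE]
}

#' Joint dosage counts for a marker pair
#'
#' @param x A `dosage_matrix`.
#' @param m1,m2 Marker names or row indices.
#' @return 5 x 5 matrix of offspring counts over joint dosage classes
#'   (rows: dosage of `m1` 0..4; columns: `m2`), non-missing pairs only.
#' @export
joint_counts <- function(x, m1, m2) {
  stopifnot(inherits(x, "dosage_matrix"))
  d1 <- unclass(x)[m1, ]
  d2 <- unclass(x)[m2, ]
  ok <- !is.na(d1) & !is.na(d2)
  tab <- matrix(0L, 5L, 5L, dimnames = list(dosage1 = 0:4, dosage2 = 0:4))
  if (any(ok)) {
    t0 <- table(factor(d1[ok], levels = 0:4), factor(d2[ok], levels = 0:4))
    tab[] <- as.integer(t0)
  }
  tab
}

#' Two-point maximum-likelihood estimation of recombination fraction and LOD
#'
#' For each candidate phase combination of the two parents, offspring
#' joint-dosage class probabilities are derived from the exact bivalent
#' gamete distributions; the likelihood is maximised over `r` in `[0, 0.5]`
#' by bounded one-dimensional optimisation (tolerance 1e-6) and the phase
#' with the highest maximised likelihood is returned, ties broken toward
#' coupling. `LOD = log10 L(r_hat) - log10 L(0.5)`.
#'
#' @param counts 5 x 5 joint dosage count matrix (see [joint_counts()]).
#' @param seg1,seg2 [classify_segregation()] results for the two markers.
#' @return Object of class `two_point_result`: `r`, `LOD`, `phase`
#'   (list with `maternal` and `paternal` [pair_phase()]), `n_used`,
#'   `loglik`.
#' @export
estimate_two_point <- function(counts, seg1, seg2) {
  stopifnot(inherits(seg1, "seg_type"), inherits(seg2, "seg_type"))
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(5L, 5L)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("no data: all joint counts are zero", call. = FALSE)
  dm1 <- seg1$maternal; dp1 <- seg1$paternal
  dm2 <- seg2$maternal; dp2 <- seg2$paternal
  m_inf <- (dm1 %in% 1:3) && (dm2 %in% 1:3)
  p_inf <- (dp1 %in% 1:3) && (dp2 %in% 1:3)
  if (!m_inf && !p_inf) {
    stop("no parent is informative for both markers; r is not estimable",
         call. = FALSE)
  }
  combos <- .phase_combos(dm1, dp1, dm2, dp2)
  cnt <- as.vector(counts)
  obs <- cnt > 0

  # data-consistency check: classes impossible under every candidate phase
  possible <- rep(FALSE, 25L)
  coeff_list <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    coeff_list[[i]] <- .offspring_coeffs_cached(
      dm1, dm2, combos$om[i], dp1, dp2, combos$op[i])
    possible <- possible | (.class_probs(coeff_list[[i]], 0.25) > 1e-12)
  }
  if (any(obs & !possible)) {
    bad <- which(obs & !possible) - 1L
    stop(sprintf(
      "counts inconsistent with segregation types %s/%s: impossible joint dosage classes (%s) observed",
      seg1$label, seg2$label,
      paste(sprintf("%d/%d", bad %% 5L, bad %/% 5L), collapse = ", ")),
      call. = FALSE)
  }

  ll_fun <- function(coeffs) {
    function(r) sum(cnt[obs] * log(pmax(.class_probs(coeffs, r)[obs], 1e-300)))
  }
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    f <- ll_fun(coeff_list[[i]])
    opt <- stats::optimize(f, c(0, 0.5), maximum = TRUE, tol = 1e-6)
    # optimise never tests the boundary itself
    cand_r <- c(0, opt$maximum, 0.5)
    cand_ll <- c(f(0), opt$objective, f(0.5))
    j <- which.max(cand_ll)
    if (is.null(best) || cand_ll[j] > best$ll + 1e-9) {
      best <- list(r = cand_r[j], ll = cand_ll[j], ll0.5 = cand_ll[3L],
                   om = combos$om[i], op = combos$op[i])
    }
  }
  lod <- max(0, (best$ll - best$ll0.5) / log(10))
  structure(list(
    r = best$r,
    LOD = lod,
    phase = list(maternal = pair_phase(dm1, dm2, best$om),
                 paternal = pair_phase(dp1, dp2, best$op)),
    n_used = n,
    loglik = best$ll
  ), class = "two_point_result")
}

#' @export
print.two_point_result <- function(x, ...) {
  cat(sprintf("<two_point> r = %.4f, LOD = %.2f, phase = %s/%s, n = %d\n",
              x$r, x$LOD, x$phase$maternal$label, x$phase$paternal$label,
              x$n_used))
  invisible(x)
}

#' Batch two-point estimation over many marker pairs
#'
#' Vectorised equivalent of [estimate_two_point()] for genome-scale pair
#' lists: pairs are grouped by segregation-type combination, likelihoods are
#' evaluated on a coarse grid from precomputed polynomial coefficients, and
#' each pair's MLE is refined by golden-section search to a tolerance of
#' 1e-6. Pairs for which no parent segregates at both markers get `r = NA`
#' and `LOD = 0`. Agrees with the single-pair optimiser to < 1e-5 in `r`.
#'
#' @param x A `dosage_matrix` with `dosage_m`/`dosage_p` attributes.
#' @param pairs Two-column matrix (or data.frame) of marker names or row
#'   indices. Required.
#' @return data.table with columns `marker1`, `marker2`, `r`, `LOD`,
#'   `phase_m`, `phase_p` (phase labels), `overlap_m`, `overlap_p`, `n`.
#' @export
estimate_two_point_batch <- function(x, pairs) {
  stopifnot(inherits(x, "dosage_matrix"))
  X <- unclass(x)
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.character(pairs)) {
    idx1 <- match(pairs[, 1L], rownames(X))
    idx2 <- match(pairs[, 2L], rownames(X))
  } else {
    idx1 <- as.integer(pairs[, 1L]); idx2 <- as.integer(pairs[, 2L])
  }
  if (anyNA(idx1) || anyNA(idx2)) stop("unknown marker in pairs", call. = FALSE)
  dm <- attr(x, "dosage_m"); dp <- attr(x, "dosage_p")
  N <- length(idx1)

  # joint dosage class code per individual: d1 + 5*d2 (NA if either missing)
  code_of <- function(i1, i2) X[i1, ] + 5L * X[i2, ]

  counts <- matrix(0L, N, 25L)
  for (k in seq_len(N)) {
    ck <- code_of(idx1[k], idx2[k])
    counts[k, ] <- tabulate(ck + 1L, nbins = 25L)
  }
  ntot <- rowSums(counts)

  key <- paste(dm[idx1], dp[idx1], dm[idx2], dp[idx2], sep = "_")
  res_r <- rep(NA_real_, N)
  res_lod <- rep(0, N)
  res_om <- rep(NA_integer_, N)
  res_op <- rep(NA_integer_, N)

  r_grid <- seq(0, 0.5, by = 0.01)
  for (kv in unique(key)) {
    sel <- which(key == kv)
    ds <- as.integer(strsplit(kv, "_", fixed = TRUE)[[1L]])
    dm1 <- ds[1L]; dp1 <- ds[2L]; dm2 <- ds[3L]; dp2 <- ds[4L]
    m_inf <- (dm1 %in% 1:3) && (dm2 %in% 1:3)
    p_inf <- (dp1 %in% 1:3) && (dp2 %in% 1:3)
    if (!m_inf && !p_inf) next
    combos <- .phase_combos(dm1, dp1, dm2, dp2)
    cm <- counts[sel, , drop = FALSE]
    best_ll <- rep(-Inf, length(sel))
    best_r <- rep(NA_real_, length(sel))
    best_om <- rep(NA_integer_, length(sel))
    best_op <- rep(NA_integer_, length(sel))
    best_llhalf <- rep(NA_real_, length(sel))
    for (i in seq_len(nrow(combos))) {
      C <- .offspring_coeffs_cached(dm1, dm2, combos$om[i],
                                    dp1, dp2, combos$op[i])
      logP <- log(pmax(C %*% t(outer(r_grid, 0:4, `^`)), 1e-300))  # 25 x G
      ll <- cm %*% logP                                            # n x G
      gi <- max.col(ll, ties.method = "first")
      ll_half <- ll[, ncol(ll)]  # this phase's likelihood at r = 0.5
      # golden-section refinement inside the bracketing grid cells
      lo <- r_grid[pmax(gi - 1L, 1L)]
      hi <- r_grid[pmin(gi + 1L, length(r_grid))]
      gr <- (sqrt(5) - 1) / 2
      ll_at <- function(r) {
        P <- pmax(C %*% t(outer(r, 0:4, `^`)), 1e-300)             # 25 x n
        rowSums(cm * t(log(P)))
      }
      a <- lo; b <- hi
      for (it in 1:40) {
        x1 <- b - gr * (b - a)
        x2 <- a + gr * (b - a)
        keep_right <- ll_at(x1) < ll_at(x2)
        a <- ifelse(keep_right, x1, a)
        b <- ifelse(keep_right, b, x2)
        if (max(b - a) < 1e-7) break
      }
      r_hat <- (a + b) / 2
      ll_hat <- ll_at(r_hat)
      # exact boundary candidates
      ll_0 <- ll[, 1L]
      ll_5 <- ll[, ncol(ll)]
      r_cand <- cbind(0, r_hat, 0.5)
      ll_cand <- cbind(ll_0, ll_hat, ll_5)
      jb <- max.col(ll_cand, ties.method = "first")
      r_i <- r_cand[cbind(seq_along(sel), jb)]
      ll_i <- ll_cand[cbind(seq_along(sel), jb)]
      upd <- ll_i > best_ll + 1e-9
      best_ll[upd] <- ll_i[upd]
      best_r[upd] <- r_i[upd]
      best_om[upd] <- combos$om[i]
      best_op[upd] <- combos$op[i]
      best_llhalf[upd] <- ll_half[upd]
    }
    res_r[sel] <- best_r
    res_lod[sel] <- pmax(0, (best_ll - best_llhalf) / log(10))
    res_om[sel] <- best_om
    res_op[sel] <- best_op
  }

  phase_label <- function(d1, d2, ov) {
    out <- rep(NA_character_, length(ov))
    ok <- !is.na(ov)
    out[ok] <- vapply(which(ok), function(i) {
      pair_phase(d1[i], d2[i], ov[i])$label
    }, character(1))
    out
  }
  mk1 <- rownames(X)[idx1]; mk2 <- rownames(X)[idx2]
  data.table::data.table(
    marker1 = mk1, marker2 = mk2,
    r = res_r, LOD = res_lod,
    phase_m = phase_label(dm[idx1], dm[idx2], res_om),
    phase_p = phase_label(dp[idx1], dp[idx2], res_op),
    overlap_m = res_om, overlap_p = res_op,
    n = ntot)
}

#' Estimate the double-reduction rate at a simplex x nulliplex marker
#'
#' Under the simulator's DR model the duplicated homologue is the simplex
#' carrier with probability 1/4, so the expected frequency of dosage-2
#' offspring at a 1x0 (or 0x1) marker is `alpha / 4`. The estimator is
#' `alpha_hat = 4 * n2 / n`, clipped to `[0, 1]`, with a Clopper-Pearson
#' interval on the dosage-2 frequency scaled by 4.
#'
#' @param dosages Offspring dosage vector (NAs ignored).
#' @param seg [classify_segregation()] of the marker; must be 1x0 or 0x1.
#' @param conf_level Confidence level (default 0.95).
#' @return list with `alpha_hat`, `ci` (length 2), `n`, `n2`.
#' @export
estimate_double_reduction <- function(dosages, seg, conf_level = 0.95) {
  stopifnot(inherits(seg, "seg_type"))
  if (!seg$label %in% c("1x0", "0x1")) {
    stop("double-reduction estimation requires a simplex x nulliplex ",
         "(1x0 or 0x1) marker, got ", seg$label, call. = FALSE)
  }
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n == 0L) stop("no non-missing dosages", call. = FALSE)
  n2 <- sum(d == 2L)
  a <- (1 - conf_level) / 2
  lo <- if (n2 == 0L) 0 else stats::qbeta(a, n2, n - n2 + 1)
  hi <- if (n2 == n) 1 else stats::qbeta(1 - a, n2 + 1, n - n2)
  list(alpha_hat = min(1, 4 * n2 / n),
       ci = pmin(1, 4 * c(lo, hi)),
       n = n, n2 = n2)
}

#' Chi-squared test for preferential pairing
#'
#' Goodness-of-fit of observed transmission counts over the three bivalent
#' pairing configurations against the uniform 1/3 expectation of fully
#' polysomic inheritance (2 degrees of freedom).
#'
#' @param counts Integer vector of length 3: meioses observed in each
#'   pairing configuration.
#' @return list with `statistic`, `df`, `p_value`, `n` and `underpowered`
#'   (TRUE when n < 30, with a warning).
#' @export
preferential_pairing_check <- function(counts) {
  if (length(counts) != 3L || any(counts < 0)) {
    stop("counts must be 3 non-negative pairing-configuration counts",
         call. = FALSE)
  }
  n <- sum(counts)
  under <- n < 30
  if (under) warning("preferential-pairing test underpowered (n < 30)")
  e <- n / 3
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2L, lower.tail = FALSE),
       n = n, underpowered = under)
}
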