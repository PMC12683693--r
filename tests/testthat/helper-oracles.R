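# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the meiosis Monte-Carlo below samples pairings /
# chromatids / recombination directly, and the N50 oracle scans partial sums.

# Monte-Carlo two-locus gamete sampler for one tetraploid parent under the
# bivalent model: pairing uniform over the 3 configurations, one chromatid
# per bivalent, carrier switch between loci with probability r.
# h: 4 x 2 binary allele matrix. Returns n x 2 gamete dosages.
mc_gametes <- function(h, r, n) {
  pairings <- list(rbind(c(1, 2), c(3, 4)),
                   rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  p <- sample.int(3L, n, replace = TRUE)
  out <- matrix(0L, n, 2L)
  for (b in 1:2) {
    h1 <- vapply(p, function(k) pairings[[k]][b, 1L], numeric(1))
    h2 <- vapply(p, function(k) pairings[[k]][b, 2L], numeric(1))
    first <- stats::runif(n) < 0.5
    src1 <- ifelse(first, h1, h2)
    rec <- stats::runif(n) < r
    src2 <- ifelse(rec, ifelse(first, h2, h1), src1)
    out[, 1L] <- out[, 1L] + h[cbind(src1, 1L)]
    out[, 2L] <- out[, 2L] + h[cbind(src2, 2L)]
  }
  out
}

# Allele matrix for a dosage/overlap configuration (same convention as the
# package: locus-1 carriers are homologues 1..d1, locus-2 carriers overlap
# the first `overlap` of them).
phase_alleles <- function(d1, d2, overlap) {
  A <- seq_len(d1)
  nonA <- setdiff(1:4, A)
  B <- c(A[seq_len(overlap)], nonA[seq_len(d2 - overlap)])
  h <- matrix(0L, 4L, 2L)
  h[A, 1L] <- 1L
  h[B, 2L] <- 1L
  h
}

# O(n^2)-ish brute-force N50/L50: try every length as a candidate N50.
n50_bruteforce <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  half <- sum(s) / 2
  for (k in seq_along(s)) {
    if (sum(s[seq_len(k)]) >= half) {
      return(list(N50 = s[k], L50 = k))
    }
  }
}

# Exhaustive minimum covering-set size over all contig subsets.
min_cover_bruteforce <- function(sets, universe) {
  ctgs <- names(sets)
  for (k in 0:length(ctgs)) {
    combs <- utils::combn(length(ctgs), k)
    for (c in seq_len(ncol(combs))) {
      got <- unique(unlist(sets[combs[, c]]))
      if (all(universe %in% got)) return(k)
    }
  }
  length(ctgs)
}

# Random BUSCO instance: n_contig contigs, n_orth orthologs, each ortholog
# hitting a geometric-ish number of contigs (possibly zero -> Missing).
random_busco_instance <- function(n_contig, n_orth) {
  ctgs <- sprintf("c%02d", seq_len(n_contig))
  rows <- list()
  sets <- stats::setNames(vector("list", n_contig), ctgs)
  for (o in seq_len(n_orth)) {
    id <- sprintf("B%03d", o)
    k <- sample(0:3, 1L, prob = c(0.15, 0.5, 0.25, 0.1))
    if (k == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        busco_id = id, status = "Missing", contig = NA_character_)
    } else {
      hit <- sample(ctgs, k)
      st <- if (k >= 2L) "Duplicated" else "Complete"
      for (h in hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          busco_id = id, status = st, contig = h)
        sets[[h]] <- c(sets[[h]], id)
      }
    }
  }
  list(records = do.call(rbind, rows), sets = sets,
       lengths = stats::setNames(sample(1000:9999, n_contig), ctgs))
}

# Check AGP rows against the emitted FASTA: every component row must
# reproduce the corresponding slice of the object sequence.
agp_consistent <- function(agp, seqs, contigs) {
  seqs <- as.character(seqs)
  for (k in seq_len(nrow(agp))) {
    row <- agp[k, ]
    slice <- substr(seqs[[row$object]], row$object_beg, row$object_end)
    if (row$component_type == "N") {
      if (slice != strrep("N", as.integer(row$component_id))) return(FALSE)
    } else {
      s <- contigs[[row$component_id]]
      if (row$orientation == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      if (slice != s) return(FALSE)
    }
  }
  ## object lengths must equal the last object_end
  for (obj in unique(agp$object)) {
    if (nchar(seqs[[obj]]) != max(agp$object_end[agp$object == obj])) {
      return(FALSE)
    }
  }
  TRUE
}

# Random dosage count table for a seg-type pair, sampled from the model at a
# random r and random phases (used by MLE-vs-grid checks).
random_count_table <- function(n = 200) {
  repeat {
    dm1 <- sample(0:2, 1L); dp1 <- sample(0:2, 1L)
    dm2 <- sample(0:2, 1L); dp2 <- sample(0:2, 1L)
    if ((dm1 %in% 1:2 && dm2 %in% 1:2) || (dp1 %in% 1:2 && dp2 %in% 1:2)) break
  }
  ov <- function(a, b) sample(seq.int(max(0L, a + b - 4L), min(a, b)), 1L)
  om <- ov(dm1, dm2); op <- ov(dp1, dp2)
  r <- stats::runif(1L, 0, 0.5)
  gm <- joint_gamete_distribution(pair_phase(dm1, dm2, om), r)
  gp <- joint_gamete_distribution(pair_phase(dp1, dp2, op), r)
  off <- matrix(0, 5L, 5L)
  for (i in 0:2) for (j in 0:2) for (k in 0:2) for (l in 0:2) {
    off[i + k + 1L, j + l + 1L] <- off[i + k + 1L, j + l + 1L] +
      gm[i + 1L, j + 1L] * gp[k + 1L, l + 1L]
  }
  cnt <- matrix(stats::rmultinom(1L, n, as.vector(off)), 5L, 5L)
  list(counts = cnt, seg1 = classify_segregation(dm1, dp1),
       seg2 = classify_segregation(dm2, dp2), r_true = r)
}

# Dense grid-search MLE for a count table, independent of the package's
# optimiser. Offspring class probabilities are exact quartics in r, so the
# grid likelihood is evaluated from a quartic interpolation of the public
# enumeration (joint_gamete_distribution) at five nodes.
grid_mle <- function(counts, seg1, seg2, step = 1e-4) {
  rs <- seq(0, 0.5, by = step)
  off_at <- function(om, op, r) {
    gm <- joint_gamete_distribution(pair_phase(seg1$maternal,
                                               seg2$maternal, om), r)
    gp <- joint_gamete_distribution(pair_phase(seg1$paternal,
                                               seg2$paternal, op), r)
    off <- matrix(0, 5L, 5L)
    for (i in 0:2) for (j in 0:2) for (k in 0:2) for (l in 0:2) {
      off[i + k + 1L, j + l + 1L] <- off[i + k + 1L, j + l + 1L] +
        gm[i + 1L, j + 1L] * gp[k + 1L, l + 1L]
    }
    as.vector(off)
  }
  nodes <- c(0, 0.125, 0.25, 0.375, 0.5)
  Vi <- solve(outer(nodes, 0:4, `^`))
  cnt <- as.vector(counts)
  obs <- cnt > 0
  best <- list(ll = -Inf, r = NA)
  for (om in seq.int(max(0L, seg1$maternal + seg2$maternal - 4L),
                     min(seg1$maternal, seg2$maternal))) {
    for (op in seq.int(max(0L, seg1$paternal + seg2$paternal - 4L),
                       min(seg1$paternal, seg2$paternal))) {
      co <- vapply(nodes, function(r) off_at(om, op, r),
                   numeric(25L)) %*% t(Vi)        # 25 x 5 coefficients
      P <- pmax(co %*% t(outer(rs, 0:4, `^`)), 1e-300)  # 25 x G
      ll <- as.vector(cnt[obs] %*% log(P[obs, , drop = FALSE]))
      k <- which.max(ll)
      if (ll[k] > best$ll) best <- list(ll = ll[k], r = rs[k])
    }
  }
  best
}

# Small deterministic simulated cross shared by several test files.
small_cross <- function(seed = 101, n_chrom = 2, n_mark = 60, n_off = 150,
                        ...) {
  cfg <- sim_config(n_chromosomes = n_chrom, n_markers_per_chrom = n_mark,
                    n_offspring = n_off, quadrivalent_rate = 0,
                    double_reduction_rate = 0, dosage_error_rate = 0,
                    missing_rate = 0, seed = seed, ...)
  parents <- simulate_parents(cfg)
  sim <- simulate_f1(parents, cfg)
  list(cfg = cfg, parents = parents, sim = sim)
}
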