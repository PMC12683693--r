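# Synthetic autotetraploid F1 crosses with a known crossover landscape.
#
# The generator emulates an outcrossing autotetraploid (2n = 4x, polysomic
# inheritance): four homologues per parent, random bivalent pairing (the
# three pairings equiprobable), an obligate crossover per bivalent plus a
# Poisson number of extras, optional quadrivalent formation with a
# centromeric pairing-partner exchange, and double-reduction (DR) gametes.
# Every stochastic event is recorded in a truth object so downstream
# estimators can be tested by parameter recovery.

# The three ways four homologues can split into two bivalents.
.PAIRINGS <- list(
  rbind(c(1L, 2L), c(3L, 4L)),
  rbind(c(1L, 3L), c(2L, 4L)),
  rbind(c(1L, 4L), c(2L, 3L))
)

#' Configuration for the autotetraploid F1 simulator
#'
#' Holds every tunable of the synthetic-cross generator. Defaults describe a
#' leek-like design: 8 chromosomes, an F1 of 187 individuals, ~140 cM
#' chromosomes (`co_rate` 2.8 crossovers per bivalent gives 50 * 2.8 = 140 cM
#' of chromatid map length), a 4.5% marginal double-reduction rate and 1%
#' dosage-call error.
#'
#' @param n_chromosomes Number of chromosomes (default 8).
#' @param chrom_length_bp Physical length per chromosome in bp (recycled).
#' @param centromere_pos Centromere position as a fraction of length, in
#'   (0, 1) (recycled; default 0.5).
#' @param n_markers_per_chrom Markers simulated per chromosome (default 200).
#' @param n_offspring F1 population size (default 187; the companion
#'   population in the study design has 248).
#' @param co_rate Mean crossovers per bivalent per meiosis (lambda). One
#'   crossover is obligate; extras are Poisson(max(lambda - 1, 0)).
#' @param co_density Crossover-position density along the chromosome:
#'   `"uniform"`, `"pericentromeric"` (concentrated at the centromere) or
#'   `"distal"` (concentrated at the telomeres).
#' @param co_concentration Concentration parameter (>= 1) of the
#'   pericentromeric/distal Beta-type density; larger = more concentrated.
#' @param quadrivalent_rate Probability `q` that a chromosome forms a
#'   quadrivalent in a given meiosis.
#' @param double_reduction_rate Marginal probability `alpha` that a gamete
#'   carries two sister-derived copies at the telomere-most locus. DR only
#'   arises in quadrivalents, so `alpha <= quadrivalent_rate` is required
#'   (conditional DR probability is `alpha / q`).
#' @param dosage_error_rate Per-call probability `epsilon` of a +/-1 dosage
#'   miscall (clipped to 0..4).
#' @param missing_rate Per-call probability `mu` of a missing dosage.
#' @param seg_mix Named proportions of marker segregation types to simulate;
#'   names are "MxP" parental-dosage labels (e.g. `"1x0"` = maternal simplex,
#'   paternal nulliplex).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 50,
#'                   n_offspring = 100, seed = 1)
#' @export
sim_config <- function(n_chromosomes = 8,
                       chrom_length_bp = 2e8,
                       centromere_pos = 0.5,
                       n_markers_per_chrom = 200,
                       n_offspring = 187,
                       co_rate = 2.8,
                       co_density = c("uniform", "pericentromeric", "distal"),
                       co_concentration = 6,
                       quadrivalent_rate = 0.2,
                       double_reduction_rate = 0.045,
                       dosage_error_rate = 0.01,
                       missing_rate = 0.03,
                       seg_mix = c("1x0" = 0.35, "0x1" = 0.35, "1x1" = 0.15,
                                   "2x0" = 0.075, "0x2" = 0.075),
                       seed = NULL) {
  co_density <- match.arg(co_density)
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1", call. = FALSE)
  if (n_markers_per_chrom < 1) {
    stop("invalid config: n_markers_per_chrom must be >= 1", call. = FALSE)
  }
  if (n_offspring < 1) stop("n_offspring must be >= 1", call. = FALSE)
  if (co_rate < 0) stop("co_rate must be >= 0", call. = FALSE)
  if (co_concentration < 1) stop("co_concentration must be >= 1", call. = FALSE)
  .assert_prob(quadrivalent_rate, "quadrivalent_rate")
  .assert_prob(double_reduction_rate, "double_reduction_rate")
  .assert_prob(dosage_error_rate, "dosage_error_rate")
  .assert_prob(missing_rate, "missing_rate")
  if (double_reduction_rate > 0 && double_reduction_rate > quadrivalent_rate) {
    stop("double_reduction_rate must not exceed quadrivalent_rate ",
         "(DR gametes only arise in quadrivalents)", call. = FALSE)
  }
  centromere_pos <- rep_len(centromere_pos, n_chromosomes)
  if (any(centromere_pos <= 0 | centromere_pos >= 1)) {
    stop("centromere_pos must lie in (0, 1)", call. = FALSE)
  }
  chrom_length_bp <- rep_len(chrom_length_bp, n_chromosomes)
  if (any(chrom_length_bp < n_markers_per_chrom)) {
    stop("chrom_length_bp too small for marker count", call. = FALSE)
  }
  mix <- seg_mix / sum(seg_mix)
  bad <- !grepl("^[0-4]x[0-4]$", names(mix))
  if (is.null(names(mix)) || any(bad)) {
    stop("seg_mix names must be dosage labels like '1x0'", call. = FALSE)
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    centromere_pos = centromere_pos,
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    n_offspring = as.integer(n_offspring),
    co_rate = co_rate,
    co_density = co_density,
    co_concentration = co_concentration,
    quadrivalent_rate = quadrivalent_rate,
    double_reduction_rate = double_reduction_rate,
    dosage_error_rate = dosage_error_rate,
    missing_rate = missing_rate,
    seg_mix = mix,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("  %d chromosomes x %d markers, n_offspring = %d",
              x$n_chromosomes, x$n_markers_per_chrom, x$n_offspring),
      sprintf("  co_rate = %.2f (%s), q = %.3f, alpha = %.3f, eps = %.3f, mu = %.3f",
              x$co_rate, x$co_density, x$quadrivalent_rate,
              x$double_reduction_rate, x$dosage_error_rate, x$missing_rate),
      sep = "\n")
  invisible(x)
}

#' Simulate the two phased parental genomes of an F1 cross
#'
#' Assigns marker alleles to the four homologues of each parent so that the
#' configured mixture of segregation types is realised. Carrier homologues
#' are drawn uniformly, so simplex markers are spread over all four
#' homologues of a parent.
#'
#' @param config A [sim_config()].
#' @return An object of class `parent_pair`: list with elements `maternal`
#'   and `paternal` (each a `parent_genome`: per-chromosome marker positions
#'   and a 4 x M binary allele matrix), and `markers`, a data.table with
#'   columns `marker`, `chrom`, `pos`, `dosage_m`, `dosage_p`, `segtype`.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_parents_impl(config))
}

.simulate_parents_impl <- function(config) {
  M <- config$n_markers_per_chrom
  mk_list <- vector("list", config$n_chromosomes)
  mat <- vector("list", config$n_chromosomes)
  pat <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    L <- config$chrom_length_bp[ch]
    pos <- sort(sample.int(L, M))
    types <- sample(names(config$seg_mix), M, replace = TRUE,
                    prob = config$seg_mix)
    dm <- as.integer(substr(types, 1L, 1L))
    dp <- as.integer(substr(types, 3L, 3L))
    am <- matrix(0L, 4L, M)
    ap <- matrix(0L, 4L, M)
    for (j in seq_len(M)) {
      if (dm[j] > 0L) am[sample.int(4L, dm[j]), j] <- 1L
      if (dp[j] > 0L) ap[sample.int(4L, dp[j]), j] <- 1L
    }
    nm <- sprintf("chr%02d_m%04d", ch, seq_len(M))
    mk_list[[ch]] <- data.table::data.table(
      marker = nm, chrom = ch, pos = pos,
      dosage_m = dm, dosage_p = dp, segtype = types)
    mat[[ch]] <- list(positions = pos, alleles = am, length_bp = L,
                      centromere_bp = L * config$centromere_pos[ch])
    pat[[ch]] <- list(positions = pos, alleles = ap, length_bp = L,
                      centromere_bp = L * config$centromere_pos[ch])
  }
  markers <- data.table::rbindlist(mk_list)
  structure(list(
    maternal = structure(mat, class = "parent_genome"),
    paternal = structure(pat, class = "parent_genome"),
    markers = markers
  ), class = "parent_pair")
}

# Draw k crossover positions on [0, L] from the configured density.
# pericentromeric: arm chosen proportional to arm length, distance from the
# centromere ~ Beta(1, s) scaled to the arm (piles up at the centromere);
# distal is its mirror, Beta(s, 1) (piles up at the telomere).
.draw_co_positions <- function(k, L, cen, density, s) {
  if (k == 0L) return(numeric(0))
  if (density == "uniform") return(runif(k, 0, L))
  right <- runif(k) < (L - cen) / L
  arm <- ifelse(right, L - cen, cen)
  dist <- if (density == "pericentromeric") rbeta(k, 1, s) else rbeta(k, s, 1)
  ifelse(right, cen + dist * arm, cen - dist * arm)
}

# Vectorised gamete engine for one chromosome of one parent.
# alleles: 4 x M binary; returns per-gamete dosage contributions (n x M,
# values 0..2), the transmitted-homologue origin of each of the two gamete
# chromatids (n x M integer matrices) and truth vectors.
.sim_gametes_chrom <- function(chrom, config, n, keep_co = TRUE) {
  al <- chrom$alleles
  pos <- chrom$positions
  M <- length(pos)
  L <- chrom$length_bp
  cen <- chrom$centromere_bp
  lambda_extra <- max(config$co_rate - 1, 0)

  quad <- runif(n) < config$quadrivalent_rate
  p_dr <- if (config$quadrivalent_rate > 0) {
    config$double_reduction_rate / config$quadrivalent_rate
  } else 0
  dr <- quad & (runif(n) < p_dr)
  dr_hom <- ifelse(dr, sample.int(4L, n, replace = TRUE), NA_integer_)

  origin1 <- matrix(NA_integer_, n, M)
  origin2 <- matrix(NA_integer_, n, M)
  co_list <- if (keep_co) vector("list", n) else NULL
  pairing <- sample.int(3L, n, replace = TRUE)       # bivalent pairing
  pairingR <- sample.int(3L, n, replace = TRUE)      # quad right-arm pairing

  # Transmit, for a subset of gametes, one recombinant chromatid from the
  # bivalent (h1, h2), restricted to marker columns `cols` (an arm or the
  # whole chromosome). COs are provided per gamete as a padded matrix.
  transmit <- function(idx, h1, h2, co_mat, start, cols, origin) {
    if (length(idx) == 0L || length(cols) == 0L) return(origin)
    crossings <- matrix(0L, length(idx), length(cols))
    if (ncol(co_mat) > 0L) {
      for (k in seq_len(ncol(co_mat))) {
        crossings <- crossings + outer(co_mat[, k], pos[cols], "<")
      }
    }
    from_h1 <- ((start + crossings) %% 2L) == 0L
    ori <- ifelse(from_h1, h1, h2)
    origin[idx, cols] <- ori
    origin
  }

  pad_cos <- function(counts) {
    # draw sum(counts) CO positions, return padded matrix (+Inf padding)
    tot <- sum(counts)
    xs <- .draw_co_positions(tot, L, cen, config$co_density,
                             config$co_concentration)
    kmax <- max(counts, 0L)
    m <- matrix(Inf, length(counts), kmax)
    if (tot > 0L) {
      row <- rep(seq_along(counts), counts)
      colidx <- sequence(counts)
      m[cbind(row, colidx)] <- xs
    }
    m
  }

  # A crossover involves two of the four chromatids of a bivalent, so the
  # transmitted chromatid participates in each CO with probability 1/2.
  # COs in which it does not participate are masked (set +Inf) before the
  # homologue-switch count; truth records the unthinned meiotic positions.
  thin_cos <- function(m) {
    m[is.finite(m) & runif(length(m)) < 0.5] <- Inf
    m
  }

  ## --- bivalent meioses ---------------------------------------------------
  bi <- which(!quad)
  if (length(bi)) {
    prs <- pairing[bi]
    for (b in 1:2) {
      h1 <- vapply(prs, function(p) .PAIRINGS[[p]][b, 1L], integer(1))
      h2 <- vapply(prs, function(p) .PAIRINGS[[p]][b, 2L], integer(1))
      counts <- 1L + rpois(length(bi), lambda_extra)
      com <- pad_cos(counts)
      com_t <- thin_cos(com)
      start <- sample(0:1, length(bi), replace = TRUE)
      if (b == 1L) {
        origin1 <- transmit(bi, h1, h2, com_t, start, seq_len(M), origin1)
      } else {
        origin2 <- transmit(bi, h1, h2, com_t, start, seq_len(M), origin2)
      }
      if (keep_co) {
        for (i in seq_along(bi)) {
          cop <- com[i, is.finite(com[i, ])]
          co_list[[bi[i]]] <- c(co_list[[bi[i]]], cop)
        }
      }
    }
  }

  ## --- quadrivalent, no DR: pairing-partner exchange at the centromere ----
  qn <- which(quad & !dr)
  if (length(qn)) {
    left_cols <- which(pos <= cen)
    right_cols <- which(pos > cen)
    pL <- pairing[qn]
    pR <- pairingR[qn]
    for (b in 1:2) {
      counts <- 1L + rpois(length(qn), lambda_extra)
      com <- pad_cos(counts)
      com_t <- thin_cos(com)
      sL <- sample(0:1, length(qn), replace = TRUE)
      sR <- sample(0:1, length(qn), replace = TRUE)
      hL1 <- vapply(pL, function(p) .PAIRINGS[[p]][b, 1L], integer(1))
      hL2 <- vapply(pL, function(p) .PAIRINGS[[p]][b, 2L], integer(1))
      hR1 <- vapply(pR, function(p) .PAIRINGS[[p]][b, 1L], integer(1))
      hR2 <- vapply(pR, function(p) .PAIRINGS[[p]][b, 2L], integer(1))
      # right-arm crossing counts must not include left-arm COs
      cen_cross <- rowSums(matrix(com_t < cen, nrow = length(qn)))
      sR_eff <- (sR + cen_cross) %% 2L  # continue path parity into right arm
      if (b == 1L) {
        origin1 <- transmit(qn, hL1, hL2, com_t, sL, left_cols, origin1)
        origin1 <- transmit(qn, hR1, hR2, com_t, sR_eff, right_cols, origin1)
      } else {
        origin2 <- transmit(qn, hL1, hL2, com_t, sL, left_cols, origin2)
        origin2 <- transmit(qn, hR1, hR2, com_t, sR_eff, right_cols, origin2)
      }
      if (keep_co) {
        for (i in seq_along(qn)) {
          cop <- com[i, is.finite(com[i, ])]
          co_list[[qn[i]]] <- c(co_list[[qn[i]]], cop)
        }
      }
    }
  }

  ## --- double reduction: two sister-derived copies of one homologue ------
  dri <- which(dr)
  if (length(dri)) {
    origin1[dri, ] <- matrix(dr_hom[dri], length(dri), M)
    origin2[dri, ] <- matrix(dr_hom[dri], length(dri), M)
  }

  allele_at <- function(origin) {
    matrix(al[cbind(as.vector(origin), rep(seq_len(M), each = n))], n, M)
  }
  dosage <- allele_at(origin1) + allele_at(origin2)
  list(dosage = dosage, origin1 = origin1, origin2 = origin2,
       quad = quad, dr = dr, dr_homologue = dr_hom,
       pairing = ifelse(quad, NA_integer_, pairing),
       co_positions = co_list)
}

#' Simulate gametes from one parent
#'
#' Runs the meiosis engine: with probability `1 - q` the four homologues
#' form one of the three bivalent pairings uniformly at random, each
#' bivalent receives one obligate crossover plus `Poisson(lambda - 1)`
#' extras at positions drawn from the configured density, and the gamete
#' receives one recombinant chromatid per bivalent. With probability `q` a
#' quadrivalent forms (modelled as a pairing-partner exchange at the
#' centromere) and, with conditional probability `alpha / q`, the gamete is
#' a double-reduction gamete carrying two sister-derived copies of a single
#' homologue.
#'
#' @param parent A `parent_genome` (one element of [simulate_parents()]).
#' @param config A [sim_config()].
#' @param n Number of gametes to draw.
#' @param chromosomes Chromosome indices to simulate (default all).
#' @return A list with one element per chromosome, each as returned by the
#'   internal engine: `dosage` (n x M gamete allele counts, 0..2),
#'   `origin1`/`origin2` (transmitted homologue per marker per chromatid),
#'   `quad`, `dr`, `dr_homologue`, `pairing`, `co_positions`.
#' @export
simulate_gametes <- function(parent, config, n = 1,
                             chromosomes = NULL) {
  stopifnot(inherits(parent, "parent_genome"), inherits(config, "sim_config"))
  chromosomes <- chromosomes %||% seq_along(parent)
  out <- lapply(chromosomes, function(ch) {
    .sim_gametes_chrom(parent[[ch]], config, n)
  })
  names(out) <- paste0("chr", chromosomes)
  out
}

#' Simulate an F1 population and its ground truth
#'
#' Offspring dosages are the sum of one maternal and one paternal gamete
#' contribution per marker. Dosage miscalls (+/-1, clipped to 0..4) are then
#' applied at rate `epsilon` and entries are set missing at rate `mu`; the
#' truth object retains the pre-error dosages and all meiotic events.
#'
#' @param parents A `parent_pair` from [simulate_parents()].
#' @param config A [sim_config()].
#' @return A list with `dosage`, a `dosage_matrix` (integer markers x
#'   individuals matrix with attributes `dosage_m`, `dosage_p`, `markers`),
#'   and `truth`, a `sim_truth` holding per-chromosome maternal/paternal
#'   meiosis records and the error-free dosage matrix.
#' @export
simulate_f1 <- function(parents, config) {
  stopifnot(inherits(parents, "parent_pair"), inherits(config, "sim_config"))
  seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  with_seed(seed, .simulate_f1_impl(parents, config))
}

.simulate_f1_impl <- function(parents, config) {
  n <- config$n_offspring
  mk <- parents$markers
  chroms <- seq_along(parents$maternal)
  dosage <- matrix(NA_integer_, nrow(mk), n)
  truth_chr <- vector("list", length(chroms))
  row0 <- 0L
  for (ch in chroms) {
    gm <- .sim_gametes_chrom(parents$maternal[[ch]], config, n)
    gp <- .sim_gametes_chrom(parents$paternal[[ch]], config, n)
    M <- ncol(gm$dosage)
    dosage[row0 + seq_len(M), ] <- t(gm$dosage + gp$dosage)
    truth_chr[[ch]] <- list(maternal = gm, paternal = gp)
    row0 <- row0 + M
  }
  rownames(dosage) <- mk$marker
  colnames(dosage) <- sprintf("F1_%03d", seq_len(n))
  true_dosage <- dosage

  eps <- config$dosage_error_rate
  if (eps > 0) {
    hit <- runif(length(dosage)) < eps
    delta <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
    dosage[hit] <- pmin(pmax(dosage[hit] + delta, 0L), 4L)
  }
  mu <- config$missing_rate
  if (mu > 0) {
    dosage[runif(length(dosage)) < mu] <- NA_integer_
  }

  dm <- structure(dosage,
                  dosage_m = stats::setNames(mk$dosage_m, mk$marker),
                  dosage_p = stats::setNames(mk$dosage_p, mk$marker),
                  markers = mk,
                  class = c("dosage_matrix", "matrix", "array"))
  truth <- structure(list(
    chromosomes = truth_chr,
    true_dosage = true_dosage,
    markers = mk,
    config = config
  ), class = "sim_truth")
  list(dosage = dm, truth = truth)
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d markers x %d individuals (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(unclass(x)))))
  invisible(x)
}

#' Realized recombination counts between adjacent markers
#'
#' Counts, from the simulation truth, the homologue exchanges between
#' adjacent markers across all transmitted chromatids of one parent; the
#' realized recombination frequency per interval is the exchange count over
#' the number of chromatids. Used for map-length recovery checks.
#'
#' @param truth A `sim_truth` from [simulate_f1()].
#' @param chrom Chromosome index.
#' @param parent `"maternal"` or `"paternal"`.
#' @return data.table with `interval` (left marker index), `n_chromatids`,
#'   `n_exchanges` and `freq`.
#' @export
true_recombination_counts <- function(truth, chrom = 1,
                                      parent = c("maternal", "paternal")) {
  stopifnot(inherits(truth, "sim_truth"))
  parent <- match.arg(parent)
  g <- truth$chromosomes[[chrom]][[parent]]
  count_one <- function(o) colSums(o[, -1L, drop = FALSE] !=
                                   o[, -ncol(o), drop = FALSE])
  ex <- count_one(g$origin1) + count_one(g$origin2)
  n_chromatids <- 2L * nrow(g$origin1)
  data.table::data.table(interval = seq_along(ex), n_chromatids = n_chromatids,
                         n_exchanges = as.integer(ex),
                         freq = ex / n_chromatids)
}
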