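# Alignment filtering, contig placement, pseudomolecule construction,
# Marey-map landscape statistics and marker-based synteny.

aln_row <- function(marker, contig, start = 1, end = 70, strand = "+",
                    coverage = 1, identity = 1, n_hits = 1) {
  data.table::data.table(marker = marker, contig = contig, start = start,
                         end = end, strand = strand, coverage = coverage,
                         identity = identity, n_hits = n_hits)
}

test_that("filter_alignments applies the retention rules in order", {
  al <- rbind(
    aln_row("m1", "c1", coverage = 0.97),              # coverage
    aln_row("m2", "c1", identity = 0.94),              # identity
    aln_row("m3", "c1", n_hits = 2),                   # ambiguity
    aln_row("m4", "c1", n_hits = 5),                   # hit-count
    aln_row("m5", "c1", coverage = 1.0, identity = 0.96))  # retained
  fa <- filter_alignments(al)
  expect_equal(unname(fa$ledger[c("coverage", "identity", "ambiguity",
                                  "hit_count", "retained")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(fa$retained$marker, "m5")

  ## per-contig cap keeps the highest-identity probes
  many <- do.call(rbind, lapply(1:10, function(i) {
    aln_row(sprintf("p%02d", i), "cA", identity = 0.95 + i / 1000)
  }))
  fa2 <- filter_alignments(many, max_probes_per_contig = 4)
  expect_equal(unname(fa2$ledger["contig_cap"]), 6L)
  expect_setequal(fa2$retained$marker, sprintf("p%02d", 7:10))

  ## empty retention warns
  expect_warning(filter_alignments(aln_row("m1", "c1", coverage = 0)),
                 "no alignments")
})

test_that("place_contigs votes, orders, orients and logs conflicts", {
  map <- data.table::data.table(
    marker = sprintf("m%02d", 1:10),
    linkage_group = rep(1:2, each = 5),
    position_cM = c(0, 5, 10, 15, 20, 0, 5, 10, 15, 20))
  al <- rbind(
    aln_row("m01", "ctgA", start = 100, end = 170),
    aln_row("m02", "ctgA", start = 900, end = 970),
    aln_row("m03", "ctgB", start = 500, end = 570),
    aln_row("m04", "ctgB", start = 100, end = 170),
    aln_row("m05", "ctgC", start = 10, end = 80),     # single marker
    ## ctgD: 1 marker on LG1, 1 on LG2 -> tie -> conflict
    aln_row("m06", "ctgD", start = 10, end = 80),
    aln_row("m07", "ctgD", start = 400, end = 470))
  al2 <- data.table::copy(al)
  al2$marker[al2$contig == "ctgD"] <- c("m01", "m06")
  lens <- c(ctgA = 1000, ctgB = 1000, ctgC = 100, ctgD = 500, ctgE = 50)
  pl <- place_contigs(al2, map, lens)
  expect_equal(pl$conflicts, "ctgD")
  expect_true("ctgE" %in% pl$unplaced)
  pA <- pl$placements[pl$placements$contig == "ctgA", ]
  expect_equal(pA$orientation, "+")        # bp and cM increase together
  pB <- pl$placements[pl$placements$contig == "ctgB", ]
  expect_equal(pB$orientation, "-")        # bp decreases as cM increases
  pC <- pl$placements[pl$placements$contig == "ctgC", ]
  expect_equal(pC$orientation, "unoriented")
  ## order by mean cM within the chromosome
  lg1 <- pl$placements[pl$placements$chromosome == 1, ]
  expect_equal(lg1$contig[order(lg1$order)],
               lg1$contig[order(lg1$mean_cM)])
})

test_that("pseudomolecules concatenate, gap and reverse-complement correctly", {
  pl <- data.table::data.table(
    contig = c("c1", "c2", "c3"), chromosome = c(1L, 1L, 2L),
    order = c(1L, 2L, 1L), orientation = c("+", "-", "unoriented"),
    n_markers = c(2L, 2L, 1L), mean_cM = c(1, 2, 1))
  seqs <- c(c1 = "AAAA", c2 = "ACGT", c3 = "GGGG")
  ps <- build_pseudomolecules(pl, seqs, gap_length = 5)
  out <- as.character(ps$sequences)
  expect_equal(out[["chr1"]], paste0("AAAA", "NNNNN", "ACGT"))
  expect_equal(out[["chr2"]], "GGGG")                   # single contig: 0 Ns
  expect_true(grepl("ACGT", out[["chr1"]]))             # revcomp of ACGT
  expect_true(agp_consistent(ps$agp, ps$sequences, seqs))
  expect_error(build_pseudomolecules(pl, seqs[-2]), "missing contig")

  ## AGP round-trips through its writer/reader
  f <- tempfile(fileext = ".agp")
  write_agp(ps$agp, f)
  back <- read_agp(f)
  expect_equal(back$object, ps$agp$object)
  expect_equal(back$object_end, ps$agp$object_end)
  expect_equal(back$orientation, ps$agp$orientation)
})

test_that("AGP/FASTA stay mutually consistent on random placements", {
  set.seed(31)
  for (rep in 1:5) {
    n_ctg <- sample(4:12, 1)
    lens <- sample(20:60, n_ctg, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    names(seqs) <- sprintf("t%02d", seq_len(n_ctg))
    chrom <- sort(sample(1:3, n_ctg, replace = TRUE))
    pl <- data.table::data.table(
      contig = names(seqs), chromosome = chrom,
      orientation = sample(c("+", "-", "unoriented"), n_ctg, replace = TRUE),
      n_markers = 2L, mean_cM = seq_len(n_ctg))
    pl$order <- stats::ave(seq_len(nrow(pl)), pl$chromosome,
                           FUN = seq_along)
    ps <- build_pseudomolecules(pl, seqs, gap_length = 7)
    expect_true(agp_consistent(ps$agp, ps$sequences, seqs))
    ## no loss, no duplication: placed length + gaps = object lengths
    n_junction <- sum(table(chrom) - 1L)
    expect_equal(sum(Biostrings::width(ps$sequences)),
                 sum(lens) + 7L * n_junction)
  }
})

test_that("marey_stats computes rho, C and the landscape class", {
  ## perfectly collinear map: rho = 1
  map <- data.table::data.table(marker = sprintf("m%02d", 1:20),
                                linkage_group = 1L,
                                position_cM = seq(0, 95, by = 5))
  phys <- data.table::data.table(marker = map$marker, chrom = 1L,
                                 pos = seq(1e6, 20e6, length.out = 20))
  st <- marey_stats(map, phys)
  expect_equal(st$rho, 1)
  expect_equal(st$C, 1 / 3, tolerance = 0.08)

  ## reversing the physical axis leaves C unchanged
  phys_rev <- data.table::copy(phys)
  phys_rev$pos <- max(phys$pos) - phys$pos + 1e6
  st_rev <- marey_stats(map, phys_rev)
  expect_equal(st_rev$C, st$C, tolerance = 1e-6)
  expect_equal(st_rev$rho, 1)

  ## sigmoid map (recombination near the centre) classifies proximal
  x <- seq(0, 1, length.out = 30)
  sig <- 1 / (1 + exp(-14 * (x - 0.5)))
  map_s <- data.table::data.table(marker = sprintf("s%02d", 1:30),
                                  linkage_group = 1L,
                                  position_cM = 140 * (sig - min(sig)) /
                                    diff(range(sig)))
  phys_s <- data.table::data.table(marker = map_s$marker, chrom = 1L,
                                   pos = x * 2e8 + 1)
  st_s <- marey_stats(map_s, phys_s)
  expect_gt(st_s$C, 0.5)
  expect_equal(st_s$class, "proximal")

  ## degenerate physical coordinates error out
  bad <- data.table::copy(phys)
  bad$pos <- 5
  expect_error(marey_stats(map, bad), "one physical position")
})

test_that("synteny_compare finds constructed inversions and translocations", {
  n <- 90
  a <- data.table::data.table(marker = sprintf("m%03d", 1:n),
                              chrom = 1L, pos = seq_len(n) * 1e5)
  b <- data.table::copy(a)
  ## identical orders: no inversions
  s0 <- synteny_compare(a, b)
  expect_equal(nrow(s0$inversions), 0L)
  expect_equal(nrow(s0$translocations), 0L)

  ## reverse the middle third (30 markers): exactly one inversion run
  idx <- 31:60
  b2 <- data.table::copy(b)
  b2$pos[idx] <- rev(b2$pos[idx])
  s1 <- synteny_compare(a, b2)
  expect_equal(nrow(s1$inversions), 1L)
  expect_equal(s1$inversions$n_markers, 30L)
  expect_equal(s1$inversions$start_marker, "m031")
  expect_equal(s1$inversions$end_marker, "m060")

  ## two markers moved to another chromosome: translocation candidates
  b3 <- data.table::copy(b)
  b3$chrom[c(10, 50)] <- 2L
  s2 <- synteny_compare(a, b3)
  expect_equal(sort(s2$translocations$marker), c("m010", "m050"))

  ## too few shared markers warns and returns empty
  expect_warning(s3 <- synteny_compare(a[1:3, ], b[1:3, ]), "shared markers")
  expect_equal(nrow(s3$inversions), 0L)
})
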