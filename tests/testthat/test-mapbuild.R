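# Map construction: filtering/binning, clustering, homologues, ordering.

make_dosage <- function(X, dm, dp) {
  rownames(X) <- names(dm) <- names(dp) <- sprintf("m%02d", seq_len(nrow(X)))
  colnames(X) <- sprintf("I%02d", seq_len(ncol(X)))
  structure(X, dosage_m = dm, dosage_p = dp, markers = NULL,
            class = c("dosage_matrix", "matrix", "array"))
}

test_that("filter_and_bin applies thresholds, merges duplicates, bins markers", {
  set.seed(5)
  X <- matrix(sample(0:1, 10 * 20, replace = TRUE), 10, 20)
  X[2, ] <- X[1, ]                      # duplicate marker
  X[3, 1:12] <- NA                      # 60% missing
  dm <- rep(1L, 10); dp <- rep(0L, 10)
  x <- make_dosage(X, dm, dp)
  fb <- filter_and_bin(x, marker_missing_max = 0.1)
  expect_true("m03" %in% fb$removed_markers)
  expect_true(any(lengths(fb$bins) == 2L))
  bin2 <- fb$bins[[which(lengths(fb$bins) == 2L)[1]]]
  expect_setequal(bin2, c("m01", "m02"))

  ## injected duplicate individuals are merged, others are not
  z <- small_cross(seed = 71, n_chrom = 1, n_mark = 60, n_off = 60)
  X2 <- unclass(z$sim$dosage)
  X2 <- cbind(X2, dup1 = X2[, 3], dup2 = X2[, 10])
  x2 <- structure(X2, dosage_m = attr(z$sim$dosage, "dosage_m"),
                  dosage_p = attr(z$sim$dosage, "dosage_p"),
                  markers = NULL,
                  class = c("dosage_matrix", "matrix", "array"))
  fb2 <- filter_and_bin(x2)
  merged_from <- vapply(fb2$merged_individuals, `[[`, "", "dropped")
  expect_setequal(merged_from, c("dup1", "dup2"))
  expect_equal(ncol(fb2$matrix), 60L)

  ## all markers filtered -> error
  Xbad <- matrix(NA_integer_, 3, 10)
  expect_error(filter_and_bin(make_dosage(Xbad, rep(1L, 3), rep(0L, 3))),
               "all markers removed")
})

test_that("impossible dosage calls are masked before estimation", {
  set.seed(9)
  X <- matrix(sample(0:1, 40, replace = TRUE), 4, 10)
  X[1, 1] <- 4L   # impossible for a 1x0 marker
  x <- make_dosage(X, rep(1L, 4), rep(0L, 4))
  fb <- filter_and_bin(x, marker_missing_max = 0.5,
                       indiv_missing_max = 0.5,
                       duplicate_indiv_threshold = 1)
  expect_true(is.na(unclass(fb$matrix)["m01", 1]))
})

test_that("linkage-group clustering recovers chromosomes and flags strays", {
  z <- small_cross(seed = 81, n_chrom = 2, n_mark = 50, n_off = 187)
  x <- z$sim$dosage
  dm <- attr(x, "dosage_m"); dp <- attr(x, "dosage_p")
  simplex <- rownames(x)[dm == 1L & dp == 0L]
  prs <- t(utils::combn(simplex, 2))
  pw <- estimate_two_point_batch(x, prs)
  cl <- cluster_linkage_groups(pw, n_groups = 2)
  truth <- z$parents$markers$chrom[match(names(cl$groups),
                                         z$parents$markers$marker)]
  expect_equal(length(unique(cl$groups)), 2L)
  ## no cross-assignment: each group maps to exactly one chromosome
  tab <- table(cl$groups, truth)
  expect_true(all(rowSums(tab > 0) == 1L))

  ## unlinked singleton is flagged unassigned
  pw2 <- rbind(pw, data.table::data.table(
    marker1 = "stray", marker2 = simplex[1], r = NA_real_, LOD = 0,
    phase_m = NA_character_, phase_p = NA_character_,
    overlap_m = NA_integer_, overlap_p = NA_integer_, n = 0L),
    fill = TRUE)
  cl2 <- cluster_linkage_groups(pw2, n_groups = 2)
  expect_true("stray" %in% cl2$unassigned)

  ## unattainable group count -> structure error
  expect_error(cluster_linkage_groups(pw, n_groups = 40), "linkage groups")
})

test_that("homologue assignment matches simulation truth up to relabelling", {
  z <- small_cross(seed = 85, n_chrom = 1, n_mark = 80, n_off = 250)
  x <- z$sim$dosage
  dm <- attr(x, "dosage_m"); dp <- attr(x, "dosage_p")
  mks <- rownames(x)
  prs <- t(utils::combn(mks, 2))
  pw <- estimate_two_point_batch(x, prs)
  ha <- assign_homologues(x, mks, pw)
  ## truth: carrier homologue of each maternal simplex marker
  al <- z$parents$maternal[[1]]$alleles
  idx <- match(names(ha$maternal), z$parents$markers$marker)
  true_hom <- apply(al[, idx, drop = FALSE], 2, which.max)
  names(true_hom) <- names(ha$maternal)
  tab <- table(ha$maternal, true_hom)
  ## permutation match: every cluster hits exactly one true homologue
  expect_true(all(rowSums(tab > 0) == 1L))
  expect_lte(length(unique(ha$maternal)), 4L)

  ## markers all on one homologue -> a single coupling cluster
  one <- names(true_hom)[true_hom == true_hom[1]]
  ha1 <- assign_homologues(x, one, pw)
  expect_equal(length(unique(ha1$maternal)), 1L)

  ## no 1x1 bridge markers -> matching undetermined
  no_bridge <- mks[!(dm == 1L & dp == 1L)]
  expect_message(
    ha2 <- assign_homologues(x, no_bridge,
                             pw[pw$marker1 %in% no_bridge &
                                pw$marker2 %in% no_bridge, ]),
    "undetermined")
  expect_null(ha2$bridge)
})

test_that("order_markers reproduces Haldane positions and triangle order", {
  ## two markers at r = 0.1: positions 0 and -50 ln(0.8) = 11.157 cM
  pw <- data.table::data.table(
    marker1 = "a", marker2 = "b", r = 0.1, LOD = 10,
    phase_m = "coupling", phase_p = NA, n = 100L)
  om <- order_markers(pw, c("a", "b"))
  expect_equal(sort(om$map$position_cM), c(0, -50 * log(0.8)),
               tolerance = 1e-6)

  ## triangle r_AB = r_BC = 0.1, r_AC = 0.18: B must sit between A and C
  pw3 <- data.table::data.table(
    marker1 = c("A", "B", "A"), marker2 = c("B", "C", "C"),
    r = c(0.1, 0.1, 0.18), LOD = c(10, 10, 8),
    phase_m = "coupling", phase_p = NA, n = 100L)
  om3 <- order_markers(pw3, c("A", "B", "C"))
  mid <- om3$map$marker[rank(om3$map$position_cM) == 2]
  expect_equal(mid, "B")

  ## disconnected graph -> ordering error
  pw_dis <- data.table::data.table(
    marker1 = c("A", "C"), marker2 = c("B", "D"),
    r = c(0.1, 0.1), LOD = c(10, 10), phase_m = "coupling",
    phase_p = NA, n = 100L)
  expect_error(order_markers(pw_dis, c("A", "B", "C", "D")), "disconnected")
  expect_error(order_markers(pw, "a"), ">= 2 markers")
})

test_that("simulated chromosome order is recovered (tau >= 0.95, eps = 0)", {
  ## full stated marker density: sparser maps hit the tau information
  ## limit (local order below ~1 cM is unresolvable at n = 248)
  z <- small_cross(seed = 95, n_chrom = 1, n_mark = 200, n_off = 248)
  x <- z$sim$dosage
  prs <- t(utils::combn(rownames(x), 2))
  pw <- estimate_two_point_batch(x, prs)
  om <- order_markers(pw, rownames(x))
  pos_true <- z$parents$markers$pos[match(om$map$marker,
                                          z$parents$markers$marker)]
  tau <- abs(stats::cor(om$map$position_cM, pos_true, method = "kendall"))
  expect_gte(tau, 0.95)
})

test_that("map reversal and bin restoration behave as invariants require", {
  z <- small_cross(seed = 97, n_chrom = 1, n_mark = 40, n_off = 150)
  x <- z$sim$dosage
  prs <- t(utils::combn(rownames(x), 2))
  pw <- estimate_two_point_batch(x, prs)
  om <- order_markers(pw, rownames(x))
  map <- om$map
  ## reversing: total length unchanged, adjacent gaps reversed
  rev_pos <- max(map$position_cM) - map$position_cM
  expect_equal(max(rev_pos), max(map$position_cM))
  expect_equal(sort(diff(sort(rev_pos))), sort(diff(sort(map$position_cM))),
               tolerance = 1e-9)

  ## restoring bins does not move representatives
  map$linkage_group <- 1L
  bins <- list()
  bins[[map$marker[3]]] <- c(map$marker[3], "dupA", "dupB")
  restored <- restore_bins(map, bins)
  expect_equal(
    restored$position_cM[restored$marker == map$marker[3]],
    map$position_cM[3])
  expect_equal(
    restored$position_cM[restored$marker == "dupA"],
    map$position_cM[3])
  expect_equal(nrow(restored), nrow(map) + 2L)
})
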