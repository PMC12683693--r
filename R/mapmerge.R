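# Consensus-map construction over two F1 populations: pairwise linkage data
# (r, LOD per marker pair) are combined by averaging weighted with the
# squares of the LOD scores, then marker ordering and fine-tuning are rerun
# on the combined data.

#' Merge pairwise linkage data from two populations
#'
#' Marker pairs present in both sets get
#' `r_bar = (r_a LOD_a^2 + r_b LOD_b^2) / (LOD_a^2 + LOD_b^2)` and the LOD
#' averaged with the same weights; pairs present in only one set are copied
#' unchanged. Pairs shared with both LODs zero fall back to the unweighted
#' mean with a warning.
#'
#' @param a,b data.tables with columns `marker1`, `marker2`, `r`, `LOD`
#'   (as from [estimate_two_point_batch()]); unordered pairs must be unique
#'   within each set.
#' @return data.table with the merged `r` and `LOD` plus a `source` column
#'   (`"combined"`, `"a"` or `"b"`).
#' @examples
#' a <- data.table::data.table(marker1 = "m1", marker2 = "m2", r = 0.1, LOD = 3)
#' b <- data.table::data.table(marker1 = "m1", marker2 = "m2", r = 0.2, LOD = 4)
#' merge_pairwise(a, b)$r  # (0.1*9 + 0.2*16) / 25 = 0.164
#' @export
merge_pairwise <- function(a, b) {
  canon <- function(x) {
    x <- data.table::as.data.table(x)[, c("marker1", "marker2", "r", "LOD")]
    sw <- x$marker1 > x$marker2
    tmp <- x$marker1[sw]
    x$marker1[sw] <- x$marker2[sw]
    x$marker2[sw] <- tmp
    if (anyDuplicated(x[, c("marker1", "marker2")])) {
      stop("duplicate marker pairs within one linkage set", call. = FALSE)
    }
    x
  }
  a <- canon(a); b <- canon(b)
  key <- c("marker1", "marker2")
  m <- merge(a, b, by = key, all = TRUE, suffixes = c("_a", "_b"))
  shared <- !is.na(m$r_a) & !is.na(m$r_b)
  wa <- m$LOD_a^2; wb <- m$LOD_b^2
  zero <- shared & (wa + wb) == 0
  if (any(zero)) {
    warning(sprintf(
      "%d shared pair(s) with both LODs zero: unweighted mean used",
      sum(zero)))
    wa[zero] <- 1; wb[zero] <- 1
  }
  r <- ifelse(shared, (m$r_a * wa + m$r_b * wb) / (wa + wb),
              ifelse(is.na(m$r_a), m$r_b, m$r_a))
  lod <- ifelse(shared, (m$LOD_a * wa + m$LOD_b * wb) / (wa + wb),
                ifelse(is.na(m$r_a), m$LOD_b, m$LOD_a))
  data.table::data.table(
    marker1 = m$marker1, marker2 = m$marker2, r = r, LOD = lod,
    source = ifelse(shared, "combined", ifelse(is.na(m$r_a), "b", "a")))
}

#' Integrate two population maps into a consensus map
#'
#' Chromosomes represented in both populations are re-ordered from the
#' LOD^2-merged pairwise data ([merge_pairwise()] then [order_markers()]);
#' a chromosome represented in only one population is carried over
#' unchanged (the single-source rule). Population linkage groups are
#' matched by shared markers (majority vote).
#'
#' @param map_a,map_b data.tables with `marker`, `linkage_group`,
#'   `position_cM` for populations 1 and 2.
#' @param pairwise_a,pairwise_b Per-population pairwise linkage data
#'   (columns `marker1`, `marker2`, `r`, `LOD`).
#' @param stress_multiple Passed to [order_markers()].
#' @return list with `map` (consensus data.table: marker, linkage_group,
#'   position_cM, source) and `summary` (markers and length per group for
#'   consensus and both inputs).
#' @export
integrate_maps <- function(map_a, map_b, pairwise_a, pairwise_b,
                           stress_multiple = 3) {
  map_a <- data.table::as.data.table(map_a)
  map_b <- data.table::as.data.table(map_b)
  ga <- sort(unique(map_a$linkage_group))
  gb <- sort(unique(map_b$linkage_group))
  if (length(ga) == 0L && length(gb) == 0L) {
    stop("no linkage groups in either population", call. = FALSE)
  }

  ## match b's groups to a's by shared markers
  b_of_a <- stats::setNames(rep(NA_integer_, length(ga)), ga)
  if (nrow(map_b)) {
    for (g in ga) {
      mk <- map_a$marker[map_a$linkage_group == g]
      hit <- map_b$linkage_group[map_b$marker %in% mk]
      if (length(hit)) {
        b_of_a[as.character(g)] <- as.integer(names(
          sort(table(hit), decreasing = TRUE))[1L])
      }
    }
  }

  rows <- list()
  for (g in ga) {
    gb_match <- b_of_a[as.character(g)]
    mk_a <- map_a$marker[map_a$linkage_group == g]
    if (is.na(gb_match)) {
      ## single-source rule: carry population-a chromosome over unchanged
      sub <- map_a[map_a$linkage_group == g,
                   c("marker", "linkage_group", "position_cM")]
      sub$source <- "a"
      rows[[length(rows) + 1L]] <- sub
      next
    }
    mk_b <- map_b$marker[map_b$linkage_group == gb_match]
    mks <- union(mk_a, mk_b)
    sub_a <- pairwise_a[pairwise_a$marker1 %in% mks &
                        pairwise_a$marker2 %in% mks & !is.na(pairwise_a$r), ]
    sub_b <- pairwise_b[pairwise_b$marker1 %in% mks &
                        pairwise_b$marker2 %in% mks & !is.na(pairwise_b$r), ]
    mg <- merge_pairwise(sub_a, sub_b)
    ## warm-start from the input maps: where the merged data cannot
    ## distinguish orders, the consensus stays with the populations' maps
    pos_a <- stats::setNames(map_a$position_cM, map_a$marker)[mk_a]
    pos_b <- stats::setNames(map_b$position_cM, map_b$marker)[mk_b]
    ## align b to a through shared markers (shift + optional reflection)
    shared_mk <- intersect(mk_a, mk_b)
    if (length(shared_mk) >= 2L) {
      if (stats::cor(pos_a[shared_mk], pos_b[shared_mk]) < 0) {
        pos_b <- max(pos_b) - pos_b
      }
      pos_b <- pos_b + mean(pos_a[shared_mk] - pos_b[shared_mk])
    }
    init <- c(pos_a, pos_b[setdiff(mk_b, mk_a)])
    om <- order_markers(mg, intersect(mks, unique(c(mg$marker1, mg$marker2))),
                        stress_multiple = stress_multiple,
                        init_positions = init)
    mp <- om$map
    mp$linkage_group <- g
    mp$source <- "combined"
    rows[[length(rows) + 1L]] <-
      mp[, c("marker", "linkage_group", "position_cM", "source")]
  }
  ## b-only groups appended after a's groups
  g_extra <- setdiff(gb, b_of_a[!is.na(b_of_a)])
  ## only groups of b sharing no markers with any a group
  for (g in g_extra) {
    mk <- map_b$marker[map_b$linkage_group == g]
    if (any(mk %in% map_a$marker)) next
    sub <- map_b[map_b$linkage_group == g,
                 c("marker", "linkage_group", "position_cM")]
    sub$linkage_group <- max(ga, 0L) + match(g, g_extra)
    sub$source <- "b"
    rows[[length(rows) + 1L]] <- sub
  }
  consensus <- data.table::rbindlist(rows)
  data.table::setorder(consensus, linkage_group, position_cM)

  summarize <- function(m, label) {
    if (!nrow(m)) return(NULL)
    s <- data.table::as.data.table(m)[, list(markers = .N,
                                             length_cM = max(position_cM)),
                                      by = "linkage_group"]
    s$map <- label
    s
  }
  summary <- data.table::rbindlist(list(
    summarize(consensus, "integrated"),
    summarize(map_a, "population1"),
    summarize(map_b, "population2")), use.names = TRUE)
  list(map = consensus, summary = summary)
}
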