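# Map-based scaffolding: filter marker-contig alignments, place/order/orient
# contigs along the consensus genetic map, emit pseudomolecules (AGP v2.1 +
# FASTA), and characterise the recombination landscape (Marey maps) and
# marker-based synteny between assemblies.

#' Filter marker-contig alignments
#'
#' Applies the probe/alignment retention rules: minimum alignment coverage
#' and identity, a unique mapping position, a cap on genome-wide hits and a
#' per-contig probe cap (the cap keeps the highest-identity probes).
#' Rejections are categorised by the first failing rule, in the order
#' coverage, identity, ambiguity (more than one mapping position),
#' hit-count, per-contig cap.
#'
#' @param alignments data.frame/data.table with columns `marker`, `contig`,
#'   `start`, `end` (1-based inclusive), `strand`, `coverage`, `identity`,
#'   `n_hits`.
#' @param min_coverage Minimum alignment coverage (default 0.98).
#' @param min_identity Minimum alignment identity (default 0.95).
#' @param require_unique Reject markers with more than one mapping position
#'   (default TRUE).
#' @param max_hits Maximum genome-wide hit count (default 4).
#' @param max_probes_per_contig Per-contig probe cap (default 350).
#' @return list with `retained` (data.table) and `ledger` (named rejection
#'   counts: `coverage`, `identity`, `ambiguity`, `hit_count`,
#'   `contig_cap`, plus `retained`).
#' @export
filter_alignments <- function(alignments, min_coverage = 0.98,
                              min_identity = 0.95, require_unique = TRUE,
                              max_hits = 4, max_probes_per_contig = 350) {
  al <- data.table::as.data.table(alignments)
  need <- c("marker", "contig", "start", "end", "strand", "coverage",
            "identity", "n_hits")
  miss <- setdiff(need, names(al))
  if (length(miss)) {
    stop("alignments lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(al$coverage >= 0 & al$coverage <= 1),
            all(al$identity >= 0 & al$identity <= 1),
            all(al$start <= al$end), all(al$n_hits >= 1))
  ledger <- c(coverage = 0L, identity = 0L, ambiguity = 0L,
              hit_count = 0L, contig_cap = 0L, retained = 0L)
  reason <- rep(NA_character_, nrow(al))
  reason[is.na(reason) & al$coverage < min_coverage] <- "coverage"
  reason[is.na(reason) & al$identity < min_identity] <- "identity"
  if (require_unique) {
    reason[is.na(reason) & al$n_hits > 1L & al$n_hits <= max_hits] <- "ambiguity"
  }
  reason[is.na(reason) & al$n_hits > max_hits] <- "hit_count"
  ## per-contig cap keeps the highest-identity probes
  keep <- is.na(reason)
  if (any(keep)) {
    kept <- al[keep, ]
    kept$._row <- which(keep)
    data.table::setorder(kept, contig, -identity, marker)
    over <- kept[, .SD[-seq_len(min(.N, max_probes_per_contig))],
                 by = "contig"]
    if (nrow(over)) reason[over$._row] <- "contig_cap"
  }
  tab <- table(factor(reason,
                      levels = c("coverage", "identity", "ambiguity",
                                 "hit_count", "contig_cap")))
  ledger[names(tab)] <- as.integer(tab)
  retained <- al[is.na(reason), ]
  ledger["retained"] <- nrow(retained)
  if (nrow(retained) == 0L) warning("no alignments retained")
  list(retained = retained, ledger = ledger)
}

#' Place contigs on chromosomes using the genetic map
#'
#' Each contig's chromosome is the majority linkage group of its aligned
#' mapped markers (ties are unresolved conflicts: the contig is dropped and
#' logged). Contigs are ordered along a chromosome by the weighted mean cM
#' of their markers (ties broken by contig name) and oriented by the sign
#' of the rank correlation between within-contig bp and cM when at least
#' two markers with distinct cM support it, otherwise left unoriented.
#'
#' @param retained Filtered alignments ([filter_alignments()]).
#' @param map Genetic map data.table (`marker`, `linkage_group`,
#'   `position_cM`).
#' @param contig_lengths Named vector of contig lengths (bp).
#' @return list with `placements` (data.table of class info: `contig`,
#'   `chromosome`, `order`, `orientation`, `n_markers`, `mean_cM`,
#'   `length`), `conflicts` (dropped contigs), `unplaced` (contigs without
#'   marker information).
#' @export
place_contigs <- function(retained, map, contig_lengths) {
  al <- data.table::as.data.table(retained)
  map <- data.table::as.data.table(map)
  m <- merge(al, map[, c("marker", "linkage_group", "position_cM")],
             by = "marker")
  skipped <- setdiff(al$marker, map$marker)
  if (length(skipped)) {
    message(sprintf("%d aligned marker(s) absent from the map: ignored",
                    length(skipped)))
  }
  conflicts <- character(0)
  rows <- list()
  for (ctg in unique(m$contig)) {
    sub <- m[m$contig == ctg, ]
    tab <- sort(table(sub$linkage_group), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) {
      conflicts <- c(conflicts, ctg)
      next
    }
    chrom <- as.integer(names(tab)[1L])
    sub <- sub[sub$linkage_group == chrom, ]
    ori <- "unoriented"
    if (length(unique(sub$position_cM)) >= 2L) {
      mid <- (sub$start + sub$end) / 2
      rho <- suppressWarnings(stats::cor(mid, sub$position_cM,
                                         method = "spearman"))
      if (!is.na(rho) && rho > 0) ori <- "+"
      if (!is.na(rho) && rho < 0) ori <- "-"
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      contig = ctg, chromosome = chrom,
      orientation = ori, n_markers = nrow(sub),
      mean_cM = mean(sub$position_cM))
  }
  placements <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(contig = character(0), chromosome = integer(0),
                           orientation = character(0),
                           n_markers = integer(0), mean_cM = numeric(0))
  data.table::setorder(placements, chromosome, mean_cM, contig)
  if (nrow(placements)) {
    placements[, order := seq_len(.N), by = "chromosome"]
  } else {
    placements$order <- integer(0)
  }
  placements$length <- unname(contig_lengths[placements$contig])
  unplaced <- setdiff(names(contig_lengths),
                      c(placements$contig, conflicts))
  list(placements = placements, conflicts = conflicts, unplaced = unplaced)
}

#' Build pseudomolecules from contig placements
#'
#' Concatenates each chromosome's contigs in map order, reverse-complementing
#' `-` contigs and inserting unoriented contigs forward, with `gap_length`
#' N characters at every junction. Emits the chromosome sequences and a
#' consistent AGP v2.1 table.
#'
#' @param placements data.table from [place_contigs()].
#' @param contigs Contig sequences: a named character vector or a
#'   [Biostrings::DNAStringSet].
#' @param gap_length N characters per junction (default 100).
#' @return list with `sequences` (`DNAStringSet`, one per chromosome, named
#'   `chr<k>`) and `agp` (data.table with AGP v2.1 columns).
#' @export
build_pseudomolecules <- function(placements, contigs, gap_length = 100) {
  pl <- data.table::as.data.table(placements)
  if (inherits(contigs, "DNAStringSet")) {
    contigs <- as.character(contigs)
  }
  missing_ctg <- setdiff(pl$contig, names(contigs))
  if (length(missing_ctg)) {
    stop("missing contig sequence(s): ", paste(missing_ctg, collapse = ", "),
         call. = FALSE)
  }
  gap <- strrep("N", gap_length)
  seqs <- character(0)
  agp <- list()
  for (chrom in sort(unique(pl$chromosome))) {
    sub <- pl[pl$chromosome == chrom, ]
    data.table::setorder(sub, order)
    obj <- sprintf("chr%d", chrom)
    parts <- character(0)
    beg <- 1L
    part_no <- 0L
    for (k in seq_len(nrow(sub))) {
      if (k > 1L && gap_length > 0) {
        part_no <- part_no + 1L
        agp[[length(agp) + 1L]] <- data.table::data.table(
          object = obj, object_beg = beg, object_end = beg + gap_length - 1L,
          part_number = part_no, component_type = "N",
          component_id = as.character(gap_length), component_beg = "scaffold",
          component_end = "yes", orientation = "align_genus")
        parts <- c(parts, gap)
        beg <- beg + gap_length
      }
      s <- contigs[[sub$contig[k]]]
      ori <- sub$orientation[k]
      if (ori == "-") s <- .revcomp(s)
      part_no <- part_no + 1L
      agp[[length(agp) + 1L]] <- data.table::data.table(
        object = obj, object_beg = beg, object_end = beg + nchar(s) - 1L,
        part_number = part_no, component_type = "W",
        component_id = sub$contig[k], component_beg = "1",
        component_end = as.character(nchar(s)),
        orientation = if (ori == "unoriented") "?" else ori)
      parts <- c(parts, s)
      beg <- beg + nchar(s)
    }
    seqs[obj] <- paste(parts, collapse = "")
  }
  list(sequences = Biostrings::DNAStringSet(seqs),
       agp = data.table::rbindlist(agp))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Write / read an AGP v2.1 file
#'
#' @param agp data.table as produced by [build_pseudomolecules()].
#' @param path File path.
#' @return `read_agp()` returns the data.table; `write_agp()` returns the
#'   path invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  utils::write.table(agp, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = lines, header = FALSE,
                          colClasses = list(character = c(5:9)))
  data.table::setnames(dt, c("object", "object_beg", "object_end",
                             "part_number", "component_type", "component_id",
                             "component_beg", "component_end", "orientation"))
  dt
}

#' Marey-map statistics and recombination-landscape classification
#'
#' For each chromosome with genetic and physical marker coordinates:
#' Spearman's rho between the two orders; a monotone (isotonic) Marey curve
#' fitted after orienting the genetic axis so rho >= 0; the central-tertile
#' fraction `C = (cM(2L/3) - cM(L/3)) / total cM` read off the curve; and a
#' windowed cM/Mb profile. Chromosomes are classified `proximal` when
#' `C > 0.5` (recombination concentrated around the centre, as in a
#' pericentromeric landscape), `distal` when `C < 0.25`, otherwise `mixed`.
#'
#' @param map data.table with `marker`, `linkage_group`, `position_cM`.
#' @param physical data.table with `marker`, `chrom` (matching
#'   `linkage_group`), `pos` (bp).
#' @param n_windows Number of physical windows for the cM/Mb profile
#'   (default 20).
#' @param min_markers Minimum markers per chromosome (default 5).
#' @return data.table with one row per chromosome: `chromosome`,
#'   `n_markers`, `rho`, `C`, `class`, plus a `profile` attribute (list of
#'   per-window cM/Mb data.tables).
#' @export
marey_stats <- function(map, physical, n_windows = 20, min_markers = 5) {
  map <- data.table::as.data.table(map)
  physical <- data.table::as.data.table(physical)
  m <- merge(map[, c("marker", "linkage_group", "position_cM")],
             physical[, c("marker", "chrom", "pos")], by = "marker")
  m <- m[m$linkage_group == m$chrom, ]
  rows <- list()
  profiles <- list()
  for (chrom in sort(unique(m$chrom))) {
    sub <- m[m$chrom == chrom, ]
    if (nrow(sub) < min_markers) next
    if (length(unique(sub$pos)) < 2L) {
      stop(sprintf("chromosome %s: all markers at one physical position",
                   chrom), call. = FALSE)
    }
    data.table::setorder(sub, pos)
    rho <- suppressWarnings(stats::cor(sub$pos, sub$position_cM,
                                       method = "spearman"))
    g <- sub$position_cM
    if (!is.na(rho) && rho < 0) g <- max(g) - g   # orient so rho >= 0
    iso <- stats::isoreg(sub$pos, g)
    fit_x <- sub$pos
    fit_y <- iso$yf
    curve_at <- function(xq) {
      stats::approx(fit_x, fit_y, xout = xq, rule = 2, ties = mean)$y
    }
    L <- max(sub$pos)
    L0 <- min(sub$pos)
    span <- L - L0
    total <- curve_at(L) - curve_at(L0)
    C <- if (total > 0) {
      (curve_at(L0 + 2 * span / 3) - curve_at(L0 + span / 3)) / total
    } else NA_real_
    klass <- if (is.na(C)) NA_character_ else if (C > 0.5) "proximal"
             else if (C < 0.25) "distal" else "mixed"
    ## windowed cM/Mb profile
    br <- seq(L0, L, length.out = n_windows + 1L)
    prof <- data.table::data.table(
      window = seq_len(n_windows),
      start = br[-length(br)], end = br[-1L],
      cM_per_Mb = diff(curve_at(br)) / (diff(br) / 1e6))
    profiles[[as.character(chrom)]] <- prof
    rows[[length(rows) + 1L]] <- data.table::data.table(
      chromosome = chrom, n_markers = nrow(sub),
      rho = abs(rho), C = C, class = klass)
  }
  out <- data.table::rbindlist(rows)
  attr(out, "profile") <- profiles
  out
}

#' Marker-based synteny comparison between two assemblies
#'
#' For each chromosome pair sharing markers, markers are sorted by their
#' position on assembly A; maximal runs of monotone-decreasing B positions
#' of length >= `k` are reported as candidate inversions, and markers whose
#' B chromosome differs from the majority B chromosome of their A
#' chromosome are reported as translocation candidates.
#'
#' @param pos_a,pos_b data.tables with `marker`, `chrom`, `pos`.
#' @param k Minimum run length to call an inversion (default 5).
#' @return list with `shared` (merged marker table), `inversions`
#'   (data.table: chrom_a, chrom_b, start_marker, end_marker, n_markers)
#'   and `translocations` (data.table of off-chromosome markers).
#' @export
synteny_compare <- function(pos_a, pos_b, k = 5) {
  a <- data.table::as.data.table(pos_a)
  b <- data.table::as.data.table(pos_b)
  m <- merge(a, b, by = "marker", suffixes = c("_a", "_b"))
  if (nrow(m) < k) {
    warning(sprintf("fewer than k = %d shared markers", k))
    return(list(shared = m,
                inversions = data.table::data.table(),
                translocations = data.table::data.table()))
  }
  inv <- list()
  tra <- list()
  for (ca in sort(unique(m$chrom_a))) {
    sub <- m[m$chrom_a == ca, ]
    tab <- sort(table(sub$chrom_b), decreasing = TRUE)
    cb <- names(tab)[1L]
    off <- sub[sub$chrom_b != cb, ]
    if (nrow(off)) tra[[length(tra) + 1L]] <- off
    sub <- sub[sub$chrom_b == cb, ]
    data.table::setorder(sub, pos_a)
    if (nrow(sub) < k) next
    dec <- diff(sub$pos_b) < 0
    ## maximal runs of consecutive decreasing steps
    r <- rle(dec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      n_run <- r$lengths[i] + 1L   # markers in the decreasing run
      if (n_run >= k) {
        inv[[length(inv) + 1L]] <- data.table::data.table(
          chrom_a = ca, chrom_b = cb,
          start_marker = sub$marker[starts[i]],
          end_marker = sub$marker[ends[i] + 1L],
          n_markers = n_run)
      }
    }
  }
  list(shared = m,
       inversions = if (length(inv)) data.table::rbindlist(inv) else
         data.table::data.table(),
       translocations = if (length(tra)) data.table::rbindlist(tra) else
         data.table::data.table())
}
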