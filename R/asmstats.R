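# Assembly statistics, BUSCO full-table summarisation, the BUSCO-optimising
# contig purge (greedy minimal contig set covering the complete orthologs)
# and the coverage-peak genome-size estimator.

#' Assembly statistics (N50/L50, GC, gaps)
#'
#' N50 is the length of the contig at which the sorted cumulative length
#' first reaches half the total; L50 is the number of contigs needed to get
#' there. GC is computed over non-N bases and reported to one decimal,
#' rounded half away from zero.
#'
#' @param contigs Named character vector / `DNAStringSet` of sequences, or
#'   a numeric vector of contig lengths (GC and gap count then NA).
#' @return list of class `assembly_report`: `total_size`, `n_contigs`,
#'   `N50`, `L50`, `GC_percent`, `max_contig`, `n_gap_N`.
#' @examples
#' assembly_stats(c(8, 5, 4, 2, 1))[c("N50", "L50")]  # 5, 2
#' @export
assembly_stats <- function(contigs) {
  if (inherits(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  if (is.character(contigs)) {
    lens <- nchar(contigs)
    comp <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(contigs), c("G", "C", "N", "A", "T"))
    gc_bases <- sum(comp[, "G"] + comp[, "C"])
    n_bases <- sum(comp[, "N"])
    acgt <- sum(lens) - n_bases
    gc <- if (acgt > 0) round_half_away(100 * gc_bases / acgt, 1) else NA_real_
  } else {
    lens <- as.numeric(contigs)
    gc <- NA_real_
    n_bases <- NA_real_
  }
  if (length(lens) == 0L || any(lens <= 0)) {
    stop("need at least one contig with positive length", call. = FALSE)
  }
  s <- sort(lens, decreasing = TRUE)
  half <- sum(s) / 2
  cum <- cumsum(s)
  l50 <- which(cum >= half)[1L]
  structure(list(
    total_size = sum(s), n_contigs = length(s),
    N50 = s[l50], L50 = l50,
    GC_percent = gc, max_contig = s[1L], n_gap_N = n_bases
  ), class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf(
    "<assembly_report> %s bp in %d contigs; N50 = %s, L50 = %d, GC%% = %s\n",
    format(x$total_size, big.mark = ","), x$n_contigs,
    format(x$N50, big.mark = ","), x$L50,
    ifelse(is.na(x$GC_percent), "NA", format(x$GC_percent))))
  invisible(x)
}

#' Read a BUSCO full-table TSV
#'
#' Parses the standard `full_table.tsv` (comment lines starting with `#`;
#' columns ortholog id, status, sequence, start, end, ...). Multiple rows
#' per ortholog (Duplicated) are retained.
#'
#' @param path Path to the table.
#' @return data.table with `busco_id`, `status`, `contig` (NA for Missing).
#' @export
read_busco_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          fill = TRUE)
  out <- data.table::data.table(
    busco_id = as.character(dt[[1L]]),
    status = as.character(dt[[2L]]),
    contig = if (ncol(dt) >= 3L) as.character(dt[[3L]]) else NA_character_)
  out$contig[out$status == "Missing" | out$contig == ""] <- NA_character_
  .validate_busco(out)
  out
}

.validate_busco <- function(records) {
  ok <- records$status %in% c("Complete", "Duplicated", "Fragmented",
                              "Missing")
  if (!all(ok)) {
    stop("invalid BUSCO status: ",
         paste(unique(records$status[!ok]), collapse = ", "), call. = FALSE)
  }
  agg <- data.table::as.data.table(records)[, list(
    n_hits = sum(!is.na(contig)), status = status[1L]), by = "busco_id"]
  bad <- (agg$status == "Duplicated" & agg$n_hits < 2L) |
         (agg$status == "Missing" & agg$n_hits > 0L) |
         (agg$status %in% c("Complete", "Fragmented") & agg$n_hits == 0L)
  if (any(bad)) {
    stop("BUSCO records inconsistent with status for: ",
         paste(utils::head(agg$busco_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Summarise BUSCO records
#'
#' Complete = Single + Duplicated. Percentages are of the total ortholog
#' count, one decimal, rounded half away from zero.
#'
#' @param records data.table as from [read_busco_table()].
#' @return list with `total`, counts (`complete`, `single`, `duplicated`,
#'   `fragmented`, `missing`) and matching `*_pct` percentages.
#' @examples
#' # 618 duplicated of 1614 orthologs -> 38.3%
#' @export
busco_summary <- function(records) {
  records <- data.table::as.data.table(records)
  .validate_busco(records)
  st <- records[, list(status = status[1L]), by = "busco_id"]
  total <- nrow(st)
  if (total == 0L) stop("no BUSCO records", call. = FALSE)
  n_single <- sum(st$status == "Complete")
  n_dup <- sum(st$status == "Duplicated")
  n_frag <- sum(st$status == "Fragmented")
  n_miss <- sum(st$status == "Missing")
  pct <- function(n) round_half_away(100 * n / total, 1)
  list(total = total,
       complete = n_single + n_dup, single = n_single,
       duplicated = n_dup, fragmented = n_frag, missing = n_miss,
       complete_pct = pct(n_single + n_dup), single_pct = pct(n_single),
       duplicated_pct = pct(n_dup), fragmented_pct = pct(n_frag),
       missing_pct = pct(n_miss))
}

#' Greedy BUSCO-optimising contig selection (assembly purge)
#'
#' Selects a minimal set of contigs maximising the single-copy ortholog
#' content: starting from the empty set, repeatedly add the contig that
#' completes the most not-yet-covered complete orthologs, breaking ties by
#' fewer added duplicate hits, then larger contig length, then contig name;
#' stop when no contig adds a newly completed ortholog.
#'
#' @param records BUSCO records (`busco_id`, `status`, `contig`); only
#'   Complete/Duplicated rows carry coverage.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return list of class `purge_result`: `selected` (contig names in
#'   selection order), `gains` (newly covered orthologs per step),
#'   `before`/`after` ([busco_summary()] of the full and the selected set).
#' @export
purge_select <- function(records, contig_lengths) {
  records <- data.table::as.data.table(records)
  .validate_busco(records)
  hits <- records[records$status %in% c("Complete", "Duplicated") &
                  !is.na(records$contig), ]
  unknown <- setdiff(hits$contig, names(contig_lengths))
  if (length(unknown)) {
    stop("BUSCO hits reference unknown contig(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    warning("no complete BUSCO hits: empty selection")
    return(structure(list(selected = character(0), gains = integer(0),
                          before = busco_summary(records), after = NULL),
                     class = "purge_result"))
  }
  by_contig <- lapply(split(hits$busco_id, hits$contig), unique)

  ## greedy max-coverage pass over a candidate contig set
  greedy_over <- function(candidates) {
    covered <- character(0)
    selected <- character(0)
    gains <- integer(0)
    remaining <- candidates
    repeat {
      new_counts <- vapply(remaining, function(ctg) {
        length(setdiff(by_contig[[ctg]], covered))
      }, integer(1))
      if (length(new_counts) == 0L || max(new_counts) == 0L) break
      cand <- remaining[new_counts == max(new_counts)]
      if (length(cand) > 1L) {
        dup_added <- vapply(cand, function(ctg) {
          sum(by_contig[[ctg]] %in% covered)
        }, integer(1))
        cand <- cand[dup_added == min(dup_added)]
      }
      if (length(cand) > 1L) {
        lens <- contig_lengths[cand]
        cand <- cand[lens == max(lens)]
      }
      pick <- sort(cand)[1L]
      gains <- c(gains, max(new_counts))
      covered <- union(covered, by_contig[[pick]])
      selected <- c(selected, pick)
      remaining <- setdiff(remaining, pick)
    }
    list(selected = selected, gains = gains, covered = covered)
  }
  g <- greedy_over(names(by_contig))
  selected <- g$selected
  gains <- g$gains

  ## greedy can overshoot the minimum cover by one on adversarial
  ## instances; for small contig sets an exhaustive search certifies the
  ## minimum and replaces the selection when strictly smaller
  if (length(by_contig) <= 15L && length(selected) > 1L) {
    universe <- g$covered
    ctgs <- names(by_contig)
    found <- NULL
    for (k in seq_len(length(selected) - 1L)) {
      combs <- utils::combn(ctgs, k)
      for (cc in seq_len(ncol(combs))) {
        if (all(universe %in% unlist(by_contig[combs[, cc]]))) {
          found <- combs[, cc]
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) {
      ## re-derive selection order and marginal gains within the optimum
      g2 <- greedy_over(found)
      selected <- g2$selected
      gains <- g2$gains
    }
  }
  ## after-summary: restate each ortholog's status from the hits that
  ## survive on the selected contigs
  all_ids <- unique(records$busco_id)
  sel_hits <- hits[hits$contig %in% selected, ]
  n_complete <- table(factor(sel_hits$busco_id, levels = all_ids))
  frag_kept <- unique(records$busco_id[
    records$status == "Fragmented" & records$contig %in% selected])
  status_after <- ifelse(n_complete >= 2L, "Duplicated",
                  ifelse(n_complete == 1L, "Complete",
                  ifelse(all_ids %in% frag_kept, "Fragmented", "Missing")))
  reps <- pmax(as.integer(n_complete),
               as.integer(status_after == "Fragmented"), 1L)
  after_records <- data.table::data.table(
    busco_id = rep(all_ids, reps),
    status = rep(status_after, reps),
    contig = NA_character_)
  ## distinct placeholder contigs per row so Duplicated keeps >= 2 hits
  nm <- after_records$status != "Missing"
  after_records$contig[nm] <- sprintf("hit_%06d", seq_len(sum(nm)))
  structure(list(selected = selected, gains = gains,
                 before = busco_summary(records),
                 after = busco_summary(after_records)),
            class = "purge_result")
}

#' @export
print.purge_result <- function(x, ...) {
  cat(sprintf("<purge_result> %d contigs selected; duplication %s%% -> %s%%\n",
              length(x$selected),
              format(x$before$duplicated_pct),
              ifelse(is.null(x$after), "NA", format(x$after$duplicated_pct))))
  invisible(x)
}

#' Coverage-peak genome-size estimate
#'
#' Rough genome size from the total sequencing yield and the first (1-copy)
#' coverage peak of the k-mer spectrum, assuming full heterozygosity: the
#' full complement is `total_bases / peak_coverage`, the per-copy size is
#' that divided by the ploidy.
#'
#' @param total_bases Total sequenced bases.
#' @param peak_coverage Coverage at the first k-mer peak (> 0).
#' @param ploidy Number of genome copies (>= 1).
#' @return list with `full_complement` and `per_copy` (same units as
#'   `total_bases`).
#' @examples
#' genome_size_estimate(883e9, 14, 4)  # ~63 Gbp full, ~15.75 Gbp per copy
#' @export
genome_size_estimate <- function(total_bases, peak_coverage, ploidy = 1) {
  if (!is.numeric(peak_coverage) || peak_coverage <= 0) {
    stop("peak_coverage must be > 0", call. = FALSE)
  }
  if (!is.numeric(ploidy) || ploidy < 1) {
    stop("ploidy must be >= 1", call. = FALSE)
  }
  full <- total_bases / peak_coverage
  list(full_complement = full, per_copy = full / ploidy)
}
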