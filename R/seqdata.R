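#' Synthetic control-region reference and coordinate map
#'
#' The simulator and the variant caller share a concatenated control-region
#' layout: simulator positions 1-546 stand for reference positions
#' 16024-16569 (covering HVRI, 16024-16365) and positions 547-1122 stand for
#' reference positions 1-576 (covering HVRII, 73-340).  The reference
#' sequence itself is SYNTHETIC: a fixed pseudo-sequence drawn once from
#' control-region-like base frequencies, not the rCRS.  It is reproducible
#' across sessions and serves as the alignment anchor for difference coding.
#'
#' @param seq_length number of leading simulator positions to use (<= 1122).
#' @return a list with `seq` (character vector of bases), and `map`: a data
#'   frame with `sim_pos`, `ref_pos` and `region` (`"HVRI"`, `"HVRII"` or
#'   `"other"`).
#' @export
control_region_reference <- function(seq_length = 1122L) {
  stopifnot(seq_length >= 1, seq_length <= 1122)
  base <- with_seed(16024L, {
    sample(DNA_BASES, 1122L, replace = TRUE,
           prob = c(0.31, 0.33, 0.13, 0.23))
  })
  ref_pos <- c(16023L + 1:546, 1:576)
  region <- rep("other", 1122L)
  region[ref_pos >= 16024 & ref_pos <= 16365] <- "HVRI"
  region[ref_pos >= 73 & ref_pos <= 340] <- "HVRII"
  idx <- seq_len(seq_length)
  list(seq = base[idx],
       map = data.frame(sim_pos = idx, ref_pos = ref_pos[idx],
                        region = region[idx], stringsAsFactors = FALSE))
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")

#' Illustrative haplogroup diagnostic-motif table
#'
#' Diagnostic motifs for the Native American founding haplogroups (A2, B2,
#' B4b1, C1, D1, D4h3a, X2a) in a Phylotree-style difference notation.  The
#' POSITIONS follow classic control-region diagnostic sites; the ALLELES are
#' derived against the package's synthetic reference (the transition partner
#' of the reference base), so the table is illustrative and internally
#' consistent rather than an assertion about real-world motifs.  For real
#' data, supply a curated table via [read_motif_table()].
#'
#' @param reference a [control_region_reference()] list.
#' @return a named list of data frames with columns `pos` (reference
#'   coordinate) and `allele`, of class `"motif_table"`.
#' @export
default_motif_table <- function(reference = control_region_reference()) {
  positions <- list(
    A2    = c(16111, 16223, 16290, 16319, 235),
    B2    = c(16189, 16217, 499),
    B4b1  = c(16136, 16189, 16217),
    C1    = c(16223, 16298, 16325, 16327),
    D1    = c(16223, 16325, 16362),
    D4h3a = c(16223, 16241, 16301, 16362),
    X2a   = c(16213, 16278, 153))
  ref_base <- stats::setNames(reference$seq, reference$map$ref_pos)
  out <- lapply(positions, function(p) {
    p <- p[p %in% reference$map$ref_pos]  # restricted reference windows
    data.frame(pos = p,
               allele = unname(transition_partner[ref_base[as.character(p)]]),
               stringsAsFactors = FALSE)
  })
  if (any(!vapply(out, nrow, 0L))) {
    stop("reference window too short: some haplogroups lose every ",
         "diagnostic position", call. = FALSE)
  }
  structure(out, class = "motif_table")
}

#' Read / write a motif table as YAML
#'
#' The YAML maps each haplogroup label to a list of variant strings in
#' position-allele notation, e.g. `16223T`.
#'
#' @param path YAML file.
#' @return for `read_motif_table`, a `"motif_table"` list of data frames.
#' @export
read_motif_table <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty motif table", call. = FALSE)
  out <- lapply(raw, function(v) {
    v <- as.character(unlist(v))
    m <- regmatches(v, regexec("^([0-9]+)([ACGTacgt])$", v))
    bad <- vapply(m, length, 0L) != 3L
    if (any(bad)) {
      stop("malformed variant string(s): ", paste(v[bad], collapse = ", "),
           call. = FALSE)
    }
    data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
               allele = toupper(vapply(m, `[`, "", 3L)),
               stringsAsFactors = FALSE)
  })
  if (any(!vapply(out, nrow, 0L))) {
    stop("every haplogroup needs at least one diagnostic variant",
         call. = FALSE)
  }
  structure(out, class = "motif_table")
}

#' @rdname read_motif_table
#' @param motifs a `"motif_table"`.
#' @export
write_motif_table <- function(motifs, path) {
  yaml::write_yaml(lapply(motifs, function(df) paste0(df$pos, df$allele)),
                   path)
  invisible(path)
}

# Map motif reference coordinates to simulator coordinates.
motif_to_sim_coords <- function(motif, reference) {
  idx <- match(motif$pos, reference$map$ref_pos)
  if (anyNA(idx)) {
    stop("motif position(s) outside the reference map: ",
         paste(motif$pos[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  data.frame(pos = reference$map$sim_pos[idx], allele = motif$allele,
             stringsAsFactors = FALSE)
}

#' Read a FASTA alignment into a character matrix
#'
#' @param path FASTA file of pre-aligned, equal-length sequences.
#' @return character matrix (samples x sites), uppercase.
#' @export
read_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) > 1L) {
    off <- names(seqs)[lens != stats::median(lens)]
    stop("ragged alignment; offending record(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  m <- toupper(as.character(as.matrix(seqs)))
  rownames(m) <- names(seqs)
  m
}

#' Read a sample metadata table
#'
#' @param path tab-separated file with columns
#'   `sample`, `population`, `region`, `language`, `lat`, `lon`.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "region", "language", "lat", "lon")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Join an alignment with its metadata
#'
#' Fails with an explicit reconciliation error if any FASTA sample lacks a
#' metadata row.
#'
#' @param aln alignment matrix from [read_alignment()].
#' @param meta metadata from [read_metadata()].
#' @return a list with `alignment` (rows ordered as metadata) and `metadata`.
#' @export
join_dataset <- function(aln, meta) {
  orphans <- setdiff(rownames(aln), meta$sample)
  if (length(orphans)) {
    stop("sample(s) in FASTA absent from metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  meta <- meta[meta$sample %in% rownames(aln), , drop = FALSE]
  list(alignment = aln[meta$sample, , drop = FALSE], metadata = meta)
}

#' Express a sequence as differences from the reference
#'
#' EMPOP-style difference coding: one variant per site whose (unambiguous)
#' base differs from the reference.  Sites with `N` or other ambiguity codes
#' are skipped and counted; indels are outside the model (substitution-only
#' alignments).
#'
#' @param seq character vector of bases (simulator coordinates), or a single
#'   row of an alignment matrix.
#' @param reference a [control_region_reference()]; its `map` supplies
#'   reference coordinates and HVRI/HVRII flags.
#' @return data frame (`pos` in reference coordinates, `allele`, `region`)
#'   with attributes `n_skipped` (ambiguous sites) and class
#'   `"variant_profile"`.
#' @export
call_variants <- function(seq, reference = control_region_reference(length(seq))) {
  seq <- toupper(as.character(seq))
  if (length(seq) != length(reference$seq)) {
    stop("sequence length does not match the reference", call. = FALSE)
  }
  callable <- seq %in% DNA_BASES
  mism <- which(callable & seq != reference$seq)
  out <- data.frame(pos = reference$map$ref_pos[mism],
                    allele = seq[mism],
                    region = reference$map$region[mism],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!callable)
  class(out) <- c("variant_profile", "data.frame")
  out
}

#' Variant profiles for every sample of an alignment
#'
#' @param aln alignment matrix.
#' @inheritParams call_variants
#' @return named list of [call_variants()] profiles.
#' @export
profile_alignment <- function(aln,
                              reference = control_region_reference(ncol(aln))) {
  stats::setNames(
    lapply(seq_len(nrow(aln)), function(i) call_variants(aln[i, ], reference)),
    rownames(aln))
}

variant_keys <- function(profile) paste0(profile$pos, profile$allele)

#' Assign a haplogroup from diagnostic motifs
#'
#' Scores each haplogroup as the fraction of its diagnostic variants present
#' in the profile; reports the best label if its score reaches `min_score`,
#' otherwise `"unassigned"`.  Ties are broken in favour of the larger
#' diagnostic set (the more resolved label), then lexicographically.
#'
#' @param profile a [call_variants()] profile.
#' @param motifs a `"motif_table"`.
#' @param min_score minimum score for a call (default 0.8).
#' @return list with `label`, `score`, `runner_up`, `runner_up_score`.
#' @export
assign_haplogroup <- function(profile, motifs, min_score = 0.8) {
  if (!length(motifs)) stop("empty motif table", call. = FALSE)
  have <- variant_keys(profile)
  score <- vapply(motifs, function(df) {
    mean(paste0(df$pos, df$allele) %in% have)
  }, 0)
  sizes <- vapply(motifs, nrow, 0L)
  ord <- order(-score, -sizes, names(motifs))
  best <- ord[1]
  runner <- if (length(ord) > 1L) ord[2] else NA_integer_
  list(label = if (score[best] >= min_score) names(motifs)[best] else "unassigned",
       score = unname(score[best]),
       runner_up = if (!is.na(runner)) names(motifs)[runner] else NA_character_,
       runner_up_score = if (!is.na(runner)) unname(score[runner]) else NA_real_)
}

#' Haplogroup calls for a whole dataset
#'
#' @param profiles list of profiles from [profile_alignment()].
#' @inheritParams assign_haplogroup
#' @return data frame with `sample`, `haplogroup`, `score`, `runner_up`.
#' @export
call_haplogroups <- function(profiles, motifs, min_score = 0.8) {
  rows <- lapply(names(profiles), function(s) {
    h <- assign_haplogroup(profiles[[s]], motifs, min_score)
    data.frame(sample = s, haplogroup = h$label, score = h$score,
               runner_up = h$runner_up, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Haplogroup frequency table by gene counting
#'
#' Absolute counts and percentages of each haplogroup per population plus a
#' pooled `Total` column, by direct gene counting (haploid data needs no EM).
#' Percentages are `100 * count / n` rounded to one decimal.
#'
#' @param calls data frame from [call_haplogroups()] (columns `sample`,
#'   `haplogroup`), or any data frame with those columns.
#' @param populations named character vector mapping sample -> population.
#' @param drop_unassigned drop `"unassigned"` calls before counting
#'   (default `TRUE`, mirroring the exclusion of non-focal lineages from all
#'   statistics).
#' @return object of class `"frequency_table"`: list with `counts`, `percent`
#'   (haplogroups x populations + Total) and `n` per column.
#' @export
frequency_table <- function(calls, populations, drop_unassigned = TRUE) {
  stopifnot(all(calls$sample %in% names(populations)))
  pop <- populations[calls$sample]
  keep <- rep(TRUE, nrow(calls))
  if (drop_unassigned) keep <- calls$haplogroup != "unassigned"
  hg <- calls$haplogroup[keep]
  pop <- pop[keep]
  empty <- setdiff(unique(populations), unique(pop))
  if (length(empty)) {
    warning("population(s) with no counted samples excluded: ",
            paste(empty, collapse = ", "))
  }
  counts <- table(factor(hg), factor(pop))
  counts <- cbind(as.matrix(unclass(counts)), Total = rowSums(counts))
  n <- colSums(counts)
  percent <- round(100 * sweep(counts, 2, n, "/"), 1)
  structure(list(counts = counts, percent = percent, n = n),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Haplogroup frequencies (%) by gene counting; n =",
      paste(colnames(x$counts), x$n, sep = ":", collapse = ", "), "\n")
  print(x$percent)
  invisible(x)
}

#' Chi-square test of haplogroup frequency heterogeneity
#'
#' Pearson chi-square on the haplogroup x population count matrix.  Zero rows
#' and columns are dropped with a warning; cells with expected count below 1
#' set a reliability flag.
#'
#' @param tab a `"frequency_table"` or a count matrix (Total column, if
#'   present, is removed).
#' @return list with `statistic`, `df`, `p_value`, `low_expected` flag.
#' @export
haplogroup_heterogeneity <- function(tab) {
  counts <- if (inherits(tab, "frequency_table")) tab$counts else as.matrix(tab)
  counts <- counts[, setdiff(colnames(counts), "Total"), drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least 2 haplogroups and 2 populations", call. = FALSE)
  }
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning("dropping empty row(s)/column(s): ",
            paste(c(rownames(counts)[zr], colnames(counts)[zc]),
                  collapse = ", "))
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       low_expected = any(ht$expected < 1))
}

#' Collapse samples into haplotypes
#'
#' Haplotype identity is exact equality of the variant set, optionally
#' restricted to HVRI or HVRII.  Ids are canonical sorted-variant strings;
#' the all-reference haplotype is `"ref"`.
#'
#' @param profiles list of profiles from [profile_alignment()].
#' @param region one of `"full"`, `"HVRI"`, `"HVRII"`.
#' @return named character vector of haplotype ids per sample.
#' @export
collapse_haplotypes <- function(profiles, region = c("full", "HVRI", "HVRII")) {
  region <- match.arg(region)
  ids <- vapply(profiles, function(p) {
    if (region != "full") p <- p[p$region == region, , drop = FALSE]
    if (!nrow(p)) return("ref")
    paste(sort(variant_keys(p)), collapse = "_")
  }, "")
  ids
}

#' Per-population haplotype sets
#'
#' @param haplotypes named vector from [collapse_haplotypes()].
#' @param populations named sample -> population vector.
#' @return named list of unique haplotype ids per population.
#' @export
population_haplotype_sets <- function(haplotypes, populations) {
  stopifnot(all(names(haplotypes) %in% names(populations)))
  split(unname(haplotypes), populations[names(haplotypes)]) |>
    lapply(unique)
}
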