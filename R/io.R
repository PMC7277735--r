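#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' package-wide contracts: record ids must be unique and sequences must use
#' IUPAC characters only. Ids are taken as the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  # Accept both nucleotide and protein alphabets; reject anything outside
  # IUPAC nucleotide/amino-acid codes (plus gap and stop symbols).
  ok <- grepl("^[A-Z*.-]*$", seqs)
  if (any(!ok)) {
    stop("non-IUPAC characters in record(s): ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read gene annotations from GFF3
#'
#' Reads `gene` features from a GFF3 file (1-based, fully closed intervals)
#' into a gene table. Structural violations (end < start, unknown strand,
#' duplicate ids) are rejected with the offending line number rather than
#' repaired. Rows are normalised to (chromosome, start) order and given a
#' per-chromosome rank.
#'
#' Recognised attributes: `ID` (required), `group` (family group label;
#' its presence marks the gene as a focal-family member) and `species`.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `family`, `group`, `species`, `rank`.
#' @export
read_gff3 <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 9)
  if (length(bad) > 0) {
    stop("malformed GFF3 row at line ", lineno[bad[1]],
         " (expected 9 tab-separated columns)", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  sel <- m[, 3] == feature
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  if (nrow(m) == 0) {
    return(tibble(gene_id = character(), chromosome = character(),
                  start = integer(), end = integer(), strand = character(),
                  family = logical(), group = character(),
                  species = character(), rank = integer()))
  }
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop("non-numeric coordinates at line ", lineno[i], call. = FALSE)
  }
  if (any(end < start)) {
    i <- which(end < start)[1]
    stop("end < start at line ", lineno[i], call. = FALSE)
  }
  strand <- m[, 7]
  if (any(!strand %in% c("+", "-"))) {
    i <- which(!strand %in% c("+", "-"))[1]
    stop("unknown strand '", strand[i], "' at line ", lineno[i],
         call. = FALSE)
  }
  id <- parse_gff_attr(m[, 9], "ID")
  if (anyNA(id)) {
    stop("missing ID attribute at line ", lineno[which(is.na(id))[1]],
         call. = FALSE)
  }
  if (anyDuplicated(id)) {
    i <- which(duplicated(id))[1]
    stop("duplicate gene id '", id[i], "' at line ", lineno[i],
         call. = FALSE)
  }
  group <- parse_gff_attr(m[, 9], "group")
  species <- parse_gff_attr(m[, 9], "species")
  species[is.na(species)] <- "synthetic"
  ann <- tibble(
    gene_id = id, chromosome = m[, 1], start = start, end = end,
    strand = strand, family = !is.na(group), group = group,
    species = species
  )
  annotate_ranks(ann)
}

# Sort by (chromosome, start) and attach the per-chromosome gene rank used
# by micro-fragment construction.
annotate_ranks <- function(ann) {
  ann |>
    dplyr::arrange(.data$chromosome, .data$start) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Write a gene table as GFF3
#'
#' Inverse of [read_gff3()]: emits one `gene` feature per row with `ID`,
#' `group` (family members only) and `species` attributes.
#'
#' @param ann Gene table as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  attrs <- paste0("ID=", ann$gene_id,
                  ifelse(ann$family & !is.na(ann$group),
                         paste0(";group=", ann$group), ""),
                  paste0(";species=", ann$species))
  lines <- paste(ann$chromosome, "sbpmir", "gene", ann$start, ann$end, ".",
                 ann$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

HOMOLOGY_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a 12-column pairwise-homology table
#'
#' Reads the de-facto standard 12-column tabular protein-search output
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query/subject coordinates, E-value, bit score) and drops rows
#' above the E-value threshold, logging the count. Any search engine whose
#' output follows this dialect (or [internal_homology_search()]) can feed
#' the pipeline.
#'
#' @param path Path to the tabular file (no header).
#' @param max_evalue Retain rows with `evalue <= max_evalue`
#'   (default `1e-10`).
#' @return Tibble with the 12 standard columns plus `self_hit`.
#' @export
read_homology_table <- function(path, max_evalue = 1e-10) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty homology table: ", path, call. = FALSE)
    return(empty_homology_table())
  }
  tab <- readr::read_tsv(
    path, col_names = HOMOLOGY_COLS, show_col_types = FALSE,
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", pident = "d", length = "i",
      mismatch = "i", gapopen = "i", qstart = "i", qend = "i",
      sstart = "i", send = "i", evalue = "d", bitscore = "d"
    )
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop("malformed homology row at line ", probs$row[1], call. = FALSE)
  }
  if (anyNA(tab$evalue) || any(tab$evalue < 0)) {
    stop("malformed homology row at line ",
         which(is.na(tab$evalue) | tab$evalue < 0)[1], call. = FALSE)
  }
  n_in <- nrow(tab)
  tab <- dplyr::filter(tab, .data$evalue <= max_evalue)
  log_filter("homology table", n_in, nrow(tab),
             sprintf("E-value <= %g", max_evalue))
  dplyr::mutate(tab, self_hit = .data$qseqid == .data$sseqid)
}

empty_homology_table <- function() {
  tibble(qseqid = character(), sseqid = character(), pident = double(),
         length = integer(), mismatch = integer(), gapopen = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = double(), bitscore = double(),
         self_hit = logical())
}

#' Write a homology table in the 12-column dialect
#'
#' @param hits Tibble with the 12 standard columns (extra columns dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_table <- function(hits, path) {
  readr::write_tsv(hits[, HOMOLOGY_COLS], path, col_names = FALSE)
  invisible(path)
}

#' Symmetric closure of a homology table
#'
#' Adds the mirrored (subject, query) row for every hit so fragment matching
#' can treat homology as undirected. Self hits are kept once.
#'
#' @param hits Homology table.
#' @return Homology table containing both orientations of every hit.
#' @export
symmetrize_homology <- function(hits) {
  flipped <- dplyr::mutate(hits,
    tmp = .data$qseqid, qseqid = .data$sseqid, sseqid = .data$tmp,
    tmpc = .data$qstart, qstart = .data$sstart, sstart = .data$tmpc,
    tmpe = .data$qend, qend = .data$send, send = .data$tmpe
  )
  flipped <- flipped[, colnames(hits)]
  dplyr::distinct(dplyr::bind_rows(hits, flipped))
}
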