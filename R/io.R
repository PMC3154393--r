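#' Read a phosphosite observation table
#'
#' The site table is a tab-separated file with header columns
#' `protein_id`, `position`, `residue`, `source_id`; one row per
#' observation of a site by a source (replicate or publication).
#' Duplicate (site, source) rows are collapsed with a warning.
#'
#' @param path Path to a TSV file.
#' @param proteome Optional proteome (named character vector, see
#'   [read_proteome_fasta()]) used to validate residue letters.
#' @param lenient Drop-and-warn instead of erroring on proteome mismatches.
#' @return A [site_dataset()].
#' @export
read_site_table <- function(path, proteome = NULL, lenient = FALSE) {
  tab <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
               quote = "", comment.char = ""),
    error = function(e) stop_data("cannot parse site table '", path, "': ",
                                  conditionMessage(e))
  )
  req <- c("protein_id", "position", "residue", "source_id")
  if (!all(req %in% names(tab))) {
    stop_data("site table '", path, "' must have header columns: ",
              paste(req, collapse = ", "))
  }
  if (nrow(tab) > 0) {
    pos <- suppressWarnings(as.integer(tab$position))
    bad <- which(is.na(pos) | pos < 1)
    if (length(bad) > 0) {
      stop_data("malformed position in '", path, "' at line ", bad[1] + 1L)
    }
    tab$position <- pos
  }
  site_dataset(tab, proteome = proteome, lenient = lenient)
}

#' @rdname read_site_table
#' @param dataset A `site_dataset` to write.
#' @export
write_site_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "site_dataset"))
  write.table(dataset$observations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and write proteome FASTA files
#'
#' A proteome is represented as a named character vector of uppercase
#' amino-acid sequences; the id of each record is the first
#' whitespace-delimited token of its header. Non-standard letters are
#' permitted but flagged with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) stop_data("no sequences in '", path, "'")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop_data("duplicate sequence id(s) in '", path, "': ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) {
    stop_data("empty sequence(s) in '", path, "': ",
              paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  odd <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seqs)
  if (any(odd)) {
    warning(sum(odd), " sequence(s) contain non-standard letters")
  }
  seqs
}

#' @rdname read_proteome_fasta
#' @param proteome Named character vector of sequences.
#' @export
write_proteome_fasta <- function(proteome, path) {
  ss <- Biostrings::AAStringSet(unclass(proteome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a pairwise alignment from an aligned FASTA file
#'
#' The file must hold exactly two records of equal length over the
#' amino-acid alphabet plus the gap character `-`.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `aligned_pair` (see [aligned_pair()]).
#' @export
read_aligned_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) != 2) {
    stop_data("aligned FASTA '", path, "' must contain exactly 2 records, found ",
              length(ss))
  }
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  rows <- unname(toupper(as.character(ss)))
  aligned_pair(ids[1], ids[2], rows[1], rows[2])
}

#' @rdname read_aligned_fasta
#' @param pair An `aligned_pair` to write.
#' @export
write_aligned_fasta <- function(pair, path) {
  stopifnot(inherits(pair, "aligned_pair"))
  ss <- Biostrings::AAStringSet(c(pair$query_row, pair$target_row))
  names(ss) <- c(pair$query_id, pair$target_id)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a pairwise alignment object
#'
#' @param query_id,target_id Protein identifiers.
#' @param query_row,target_row Equal-length aligned rows with `-` as gap.
#' @return A list of class `aligned_pair`.
#' @export
aligned_pair <- function(query_id, target_id, query_row, target_row) {
  if (nchar(query_row) != nchar(target_row)) {
    stop_data("alignment rows differ in length (", nchar(query_row), " vs ",
              nchar(target_row), ")")
  }
  if (nchar(query_row) == 0) stop_data("empty alignment")
  ok <- paste0("^[-", paste(AA20, collapse = ""), "X]*$")
  if (!grepl(ok, query_row) || !grepl(ok, target_row)) {
    stop_data("alignment rows contain characters outside the amino-acid alphabet")
  }
  q <- strsplit(query_row, "", fixed = TRUE)[[1]]
  t <- strsplit(target_row, "", fixed = TRUE)[[1]]
  both_gap <- q == "-" & t == "-"
  if (any(both_gap)) {
    message(sum(both_gap), " gap-only column(s) in alignment ",
            query_id, " / ", target_id)
  }
  structure(list(query_id = query_id, target_id = target_id,
                 query_row = query_row, target_row = target_row),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("Pairwise alignment (", nchar(x$query_row), " columns)\n", sep = "")
  cat(" ", x$query_id, ": ", substr(x$query_row, 1, 60), "\n", sep = "")
  cat(" ", x$target_id, ": ", substr(x$target_row, 1, 60), "\n", sep = "")
  invisible(x)
}

# Shared two-column TSV reader; blank lines ignored, duplicates collapsed.
read_two_column <- function(path, col_names) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
    names(out) <- col_names
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    stop_data("'", path, "': expected 2 tab-separated columns at line ",
              which(nfield < 2)[1])
  }
  out <- data.frame(a = vapply(parts, `[[`, character(1), 1),
                    b = vapply(parts, `[[`, character(1), 2),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$a)) || any(!nzchar(out$b))) {
    stop_data("'", path, "': empty field(s)")
  }
  out <- out[!duplicated(paste(out$a, out$b, sep = "\t")), , drop = FALSE]
  rownames(out) <- NULL
  names(out) <- col_names
  out
}

#' Read ortholog and annotation tables
#'
#' Both are headerless two-column TSV files: ortholog tables pair a query
#' protein with its ortholog in the target species (Inparanoid-style
#' output); annotation tables pair a protein with a category term (a
#' kinase flag, a GO slim term, ...). Blank lines are ignored and
#' duplicate rows collapsed.
#'
#' @param path Path to a TSV file.
#' @param proteome,query_proteome,target_proteome Optional proteomes used
#'   to check that referenced ids exist.
#' @return A data frame with columns `query_id`/`target_id`
#'   (orthologs) or `protein_id`/`term` (annotations).
#' @export
read_ortholog_table <- function(path, query_proteome = NULL,
                                target_proteome = NULL) {
  out <- read_two_column(path, c("query_id", "target_id"))
  if (!is.null(query_proteome)) {
    bad <- setdiff(out$query_id, names(query_proteome))
    if (length(bad) > 0) {
      stop_data("ortholog table references unknown query protein(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (!is.null(target_proteome)) {
    bad <- setdiff(out$target_id, names(target_proteome))
    if (length(bad) > 0) {
      stop_data("ortholog table references unknown target protein(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  out
}

#' @rdname read_ortholog_table
#' @export
read_annotation_table <- function(path, proteome = NULL) {
  out <- read_two_column(path, c("protein_id", "term"))
  if (!is.null(proteome)) {
    bad <- setdiff(out$protein_id, names(proteome))
    if (length(bad) > 0) {
      warning("annotation table references ", length(bad),
              " protein(s) absent from the proteome")
    }
  }
  out
}

#' @rdname read_ortholog_table
#' @param tab A two-column data frame to write.
#' @export
write_two_column_table <- function(tab, path) {
  stopifnot(is.data.frame(tab), ncol(tab) >= 2)
  write.table(tab[, 1:2], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
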