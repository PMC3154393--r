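#' Phosphosite sets and observation datasets
#'
#' A *phosphosite* is one phosphorylated serine (S), threonine (T) or
#' tyrosine (Y) residue of a protein, identified by the triple
#' (`protein_id`, `position`, `residue`) with 1-based positions on the
#' ungapped protein sequence. An *observation* is a phosphosite together
#' with the `source_id` (technical replicate or publication) reporting it;
#' a site is counted at most once per source. A `site_dataset` is the
#' multiset of observations underlying all saturation and richness
#' analysis: the *multiplicity* of a site is the number of distinct
#' sources reporting it, and the *pool size* is the total observation
#' count (the sum of multiplicities).
#'
#' @param observations A data frame with columns `protein_id`, `position`,
#'   `residue`, `source_id`.
#' @param proteome Optional named character vector of protein sequences;
#'   when supplied, every site's residue letter is checked against the
#'   sequence.
#' @param lenient If `TRUE`, sites that fail proteome validation are
#'   dropped with a warning instead of raising an error.
#' @return An object of class `site_dataset`.
#' @examples
#' obs <- data.frame(protein_id = "p1", position = 3, residue = "Y",
#'                   source_id = c("r1", "r2", "r3"))
#' d <- site_dataset(obs)
#' pool_size(d)       # 3
#' multiplicity(d)    # one site seen by 3 sources
#' @export
site_dataset <- function(observations, proteome = NULL, lenient = FALSE) {
  req <- c("protein_id", "position", "residue", "source_id")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols) > 0) {
    stop_data("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs <- data.frame(
    protein_id = as.character(observations$protein_id),
    position = observations$position,
    residue = as.character(observations$residue),
    source_id = as.character(observations$source_id),
    stringsAsFactors = FALSE
  )
  if (nrow(obs) > 0) {
    pos <- suppressWarnings(as.integer(obs$position))
    bad <- which(is.na(pos) | pos < 1 | pos != as.numeric(obs$position))
    if (length(bad) > 0) {
      stop_data("invalid position at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
    obs$position <- pos
    bad <- which(!obs$residue %in% PHOSPHO_RESIDUES)
    if (length(bad) > 0) {
      stop_data("residue must be one of S, T, Y; offending row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
    }
    if (any(grepl("\t", obs$protein_id, fixed = TRUE))) {
      stop_data("protein ids must not contain tab characters")
    }
    key <- paste(site_key(obs$protein_id, obs$position, obs$residue),
                 obs$source_id, sep = "\t")
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " duplicate (site, source) observation(s) collapsed")
      obs <- obs[!dup, , drop = FALSE]
    }
  } else {
    obs$position <- integer(0)
  }
  if (!is.null(proteome)) {
    obs <- validate_sites(obs, proteome, lenient = lenient)
  }
  rownames(obs) <- NULL
  structure(list(observations = obs), class = "site_dataset")
}

# Check residue letters against a proteome; returns the validated rows.
validate_sites <- function(sites, proteome, lenient = FALSE) {
  if (nrow(sites) == 0) return(sites)
  seqs <- unclass(proteome)
  known <- sites$protein_id %in% names(seqs)
  len_ok <- known
  len_ok[known] <- sites$position[known] <= nchar(seqs[sites$protein_id[known]])
  letter <- rep(NA_character_, nrow(sites))
  idx <- which(len_ok)
  if (length(idx) > 0) {
    letter[idx] <- substring(seqs[sites$protein_id[idx]],
                             sites$position[idx], sites$position[idx])
  }
  ok <- len_ok & letter == sites$residue
  ok[is.na(ok)] <- FALSE
  if (all(ok)) return(sites)
  msg <- paste0(sum(!ok), " site(s) disagree with the proteome (unknown protein, ",
                "position beyond sequence end, or residue mismatch)")
  if (!lenient) {
    first <- which(!ok)[1]
    stop_data(msg, "; first offender: ",
              site_key(sites$protein_id[first], sites$position[first],
                       sites$residue[first]))
  }
  warning(msg, "; dropped (lenient mode)")
  sites[ok, , drop = FALSE]
}

#' Coerce to a canonical phosphosite set
#'
#' Accepts a `site_dataset` (its unique sites are taken) or a data frame
#' with columns `protein_id`, `position`, `residue`, and returns a
#' de-duplicated data frame of sites.
#'
#' @param x A `site_dataset` or a data frame of sites.
#' @return A data frame with columns `protein_id`, `position`, `residue`.
#' @export
as_sites <- function(x) {
  if (inherits(x, "site_dataset")) return(unique_sites(x))
  if (!is.data.frame(x)) stop_data("cannot interpret object as a set of phosphosites")
  req <- c("protein_id", "position", "residue")
  if (!all(req %in% names(x))) {
    stop_data("site set needs columns protein_id, position, residue")
  }
  out <- data.frame(protein_id = as.character(x$protein_id),
                    position = as.integer(x$position),
                    residue = as.character(x$residue),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(site_key(out$protein_id, out$position, out$residue)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname site_dataset
#' @param x,object A `site_dataset`.
#' @export
unique_sites <- function(x) {
  stopifnot(inherits(x, "site_dataset"))
  obs <- x$observations
  out <- obs[!duplicated(site_key(obs$protein_id, obs$position, obs$residue)),
             c("protein_id", "position", "residue"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname site_dataset
#' @export
multiplicity <- function(x) {
  stopifnot(inherits(x, "site_dataset"))
  obs <- x$observations
  if (nrow(obs) == 0) return(setNames(integer(0), character(0)))
  key <- site_key(obs$protein_id, obs$position, obs$residue)
  tab <- table(key)
  setNames(as.integer(tab), names(tab))
}

#' @rdname site_dataset
#' @export
pool_size <- function(x) {
  stopifnot(inherits(x, "site_dataset"))
  nrow(x$observations)
}

#' @rdname site_dataset
#' @param ... Ignored.
#' @export
print.site_dataset <- function(x, ...) {
  m <- multiplicity(x)
  cat("Phosphosite dataset:", length(m), "unique sites,",
      pool_size(x), "observations,",
      length(unique(x$observations$source_id)), "source(s)\n")
  if (length(m) > 0) {
    cat("Multiplicity: min", min(m), "/ median", stats::median(m),
        "/ max", max(m), "\n")
  }
  invisible(x)
}

# Internal: multiplicities restricted to a residue subset, as an unnamed
# integer vector (the abundance input for rarefaction and Chao1).
dataset_multiplicities <- function(dataset) {
  unname(multiplicity(dataset))
}
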