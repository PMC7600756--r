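#' ORF sequence sets
#'
#' An `orf_set` bundles the nucleotide ORF sequences of one genome with the
#' label used to refer to that genome throughout the pipeline (e.g. `"hybrid"`,
#' `"parentA"`). Sequences are stored as a named [Biostrings::DNAStringSet];
#' record order is preserved from the input file and ids are unique.
#'
#' @param seqs named character vector or `DNAStringSet` of nucleotide
#'   sequences; names are the record ids.
#' @param genome_label single non-empty string naming the genome.
#' @param desc optional character vector of per-record descriptions (the
#'   FASTA header text after the first whitespace).
#' @return An object of class `orf_set`.
#' @export
orf_set <- function(seqs, genome_label, desc = NULL) {
  if (!is.character(genome_label) || length(genome_label) != 1L ||
      !nzchar(genome_label)) {
    stopf("'genome_label' must be a single non-empty string")
  }
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (!methods::is(seqs, "DNAStringSet")) {
    stopf("'seqs' must be a character vector or DNAStringSet")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stopf("all records must carry a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stopf("duplicate id %s in genome '%s'",
          ids[duplicated(ids)][1L], genome_label)
  }
  if (any(Biostrings::width(seqs) < 1L)) {
    stopf("record %s in genome '%s' has an empty sequence",
          ids[Biostrings::width(seqs) < 1L][1L], genome_label)
  }
  if (is.null(desc)) desc <- rep("", length(seqs))
  structure(list(genome_label = genome_label, seqs = seqs,
                 desc = stats::setNames(desc, ids)),
            class = "orf_set")
}

#' @export
length.orf_set <- function(x) length(x$seqs)

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("<orf_set> genome '%s': %d ORFs, total %d nt\n",
              x$genome_label, length(x$seqs), sum(Biostrings::width(x$seqs))))
  invisible(x)
}

#' Record ids of an orf_set
#' @param x an `orf_set`.
#' @return Character vector of record ids in input order.
#' @export
orf_ids <- function(x) names(x$seqs)

## letters admitted in input sequences (IUPAC nucleotide codes, DNA)
.iupac_dna <- "ACGTRYSWKMBDHVN"

#' Read an ORF FASTA file
#'
#' Parses a multi-record nucleotide FASTA file into an [orf_set]. The header
#' token before the first whitespace becomes the record id (matching the
#' query-id convention of BLAST tabular output, so alignment hit tables join
#' back cleanly); the remainder of the header is kept as a description.
#' Sequences are uppercased.
#'
#' @param path path to a FASTA file.
#' @param genome_label genome label for the resulting set.
#' @return An [orf_set].
#' @details Duplicate ids, empty files, empty sequences and residues outside
#'   the IUPAC nucleotide alphabet are hard errors that name the offending
#'   record (and position, for bad residues).
#' @export
read_orf_fasta <- function(path, genome_label) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stopf("FASTA file '%s' contains no sequences", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stopf("duplicate id %s in FASTA file '%s'", ids[duplicated(ids)][1L], path)
  }
  txt <- toupper(as.character(raw))
  bad <- regexpr(sprintf("[^%s]", .iupac_dna), txt)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stopf("record %s: invalid residue '%s' at position %d",
          ids[i], substr(txt[i], bad[i], bad[i]), bad[i])
  }
  if (any(!nzchar(txt))) {
    stopf("record %s has an empty sequence", ids[!nzchar(txt)][1L])
  }
  orf_set(stats::setNames(txt, ids), genome_label, desc = desc)
}

#' Write an orf_set to FASTA
#'
#' @param x an [orf_set].
#' @param path output file path.
#' @param width line width for wrapped sequence lines.
#' @return Invisibly, `path`.
#' @export
write_orf_fasta <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "orf_set"))
  out <- x$seqs
  hdr <- ifelse(nzchar(x$desc), paste(names(out), x$desc), names(out))
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

#' Read / write an id-mapping table
#'
#' The mapping table links hybrid ORF ids to the parental gene id predicted
#' for them: a 3-column TSV `hybrid_id <TAB> parental_id <TAB> parent_label`
#' (the third column optional on input).
#'
#' @param path file path.
#' @return `read_id_mapping`: a data.frame with columns `hybrid_id`,
#'   `parental_id`, `parent_label`.
#' @export
read_id_mapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stopf("id mapping '%s' needs at least 2 columns", path)
  if (ncol(df) == 2L) df$V3 <- NA_character_
  df <- df[, 1:3]
  names(df) <- c("hybrid_id", "parental_id", "parent_label")
  .check_mapping(stats::setNames(df$parental_id, df$hybrid_id))
  df
}

#' @rdname read_id_mapping
#' @param mapping data.frame as returned by [read_id_mapping], or a named
#'   character vector (names = hybrid ids, values = parental ids).
#' @export
write_id_mapping <- function(mapping, path) {
  df <- .mapping_df(mapping)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.mapping_df <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("hybrid_id", "parental_id") %in% names(mapping)))
    if (is.null(mapping$parent_label)) mapping$parent_label <- NA_character_
    mapping[, c("hybrid_id", "parental_id", "parent_label")]
  } else {
    data.frame(hybrid_id = names(mapping), parental_id = unname(mapping),
               parent_label = NA_character_, stringsAsFactors = FALSE)
  }
}

.as_mapping <- function(mapping) {
  m <- if (is.data.frame(mapping)) {
    stats::setNames(mapping$parental_id, mapping$hybrid_id)
  } else if (is.character(mapping)) mapping
  else stopf("mapping must be a named character vector or data.frame")
  .check_mapping(m)
  m
}

.check_mapping <- function(m) {
  if (length(m) == 0L) return(invisible(m))
  if (is.null(names(m)) || anyDuplicated(names(m))) {
    stopf("mapping keys (hybrid ids) must be unique and named")
  }
  if (any(!nzchar(m)) || anyNA(m)) stopf("mapping contains empty parental ids")
  invisible(m)
}

#' Rewrite FASTA record ids with predicted parental gene ids
#'
#' Every record whose id is a mapping key is renamed to its parental gene id;
#' the original id is retained in the description (`old_id=...`). When several
#' hybrid ORFs map to one parental gene (extra gene copies), later occurrences
#' receive a `_copy2`, `_copy3`, ... suffix so ids stay unique, unless
#' `on_duplicate = "error"`.
#'
#' @param x an [orf_set].
#' @param mapping named character vector or mapping data.frame
#'   (see [read_id_mapping]).
#' @param policy what to do with unmapped records: `"keep"` leaves them
#'   untouched; `"tag"` keeps the id but appends `unassigned` to the
#'   description.
#' @param on_duplicate `"suffix"` disambiguates duplicate output ids with a
#'   copy suffix; `"error"` refuses them.
#' @return A new [orf_set] with identical sequences and record order.
#' @export
rewrite_fasta_ids <- function(x, mapping, policy = c("keep", "tag"),
                              on_duplicate = c("suffix", "error")) {
  stopifnot(inherits(x, "orf_set"))
  policy <- match.arg(policy)
  on_duplicate <- match.arg(on_duplicate)
  m <- .as_mapping(mapping)
  old <- orf_ids(x)
  mapped <- old %in% names(m)
  new <- ifelse(mapped, unname(m[old]), old)
  if (anyDuplicated(new)) {
    if (on_duplicate == "error") {
      stopf("mapping produces duplicate output id %s",
            new[duplicated(new)][1L])
    }
    new <- stats::ave(new, new, FUN = function(v) {
      if (length(v) > 1L) v[-1L] <- paste0(v[-1L], "_copy", seq_along(v)[-1L])
      v
    })
  }
  desc <- x$desc
  desc[mapped] <- trimws(paste0(desc[mapped], " old_id=", old[mapped]))
  if (policy == "tag") {
    desc[!mapped] <- trimws(paste(desc[!mapped], "unassigned"))
  }
  seqs <- x$seqs
  names(seqs) <- new
  orf_set(seqs, x$genome_label, desc = unname(desc))
}
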