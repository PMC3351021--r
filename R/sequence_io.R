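#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-line) FASTA file into a set of protein records, uppercases
#' the residues and handles ambiguous or non-standard codes
#' (B, Z, X, U, O, J, `*`) according to `policy`: `"drop"` excludes the whole
#' sequence, `"strip"` removes the offending residues. Each action is
#' reported via `message()` and tallied in the returned attributes.
#'
#' @param path path to a FASTA file (UTF-8, uncompressed or gzipped).
#' @param policy `"drop"` (default; sequences with non-standard residues are
#'   excluded, as the physicochemical features are defined only over the 20
#'   standard residues) or `"strip"` (non-standard residues are removed).
#' @param quiet suppress per-record messages.
#' @return A `data.frame` with columns `id`, `description`, `residues`, one
#'   row per retained record in file order, with attributes `n_dropped`
#'   (records removed under the drop policy) and `n_stripped` (residues
#'   removed under the strip policy).
#' @export
read_fasta <- function(path, policy = c("drop", "strip"), quiet = FALSE) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  check_fasta_lines(path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL

  keep <- rep(TRUE, length(seqs))
  n_stripped <- 0L
  bad_pat <- "[^ACDEFGHIKLMNPQRSTVWY]"
  for (i in seq_along(seqs)) {
    if (!grepl(bad_pat, seqs[i])) next
    if (policy == "drop") {
      keep[i] <- FALSE
      if (!quiet) message("dropping record '", ids[i],
                          "': non-standard residues")
    } else {
      n_bad <- nchar(seqs[i]) - nchar(gsub(bad_pat, "", seqs[i]))
      n_stripped <- n_stripped + n_bad
      seqs[i] <- gsub(bad_pat, "", seqs[i])
      if (!quiet) message("stripped ", n_bad, " residue(s) from '", ids[i], "'")
      if (!nzchar(seqs[i])) {
        keep[i] <- FALSE
        if (!quiet) message("dropping record '", ids[i],
                            "': empty after stripping")
      }
    }
  }
  out <- data.frame(id = ids[keep], description = desc[keep],
                    residues = seqs[keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "n_stripped") <- n_stripped
  out
}

# structural validation with line numbers (Biostrings reports neither)
check_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(invisible(TRUE))
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) return(invisible(TRUE))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[nonblank[1]])
    stop("malformed FASTA at line ", nonblank[1],
         ": sequence data before any '>' header", call. = FALSE)
  hdr_idx <- which(is_hdr)
  for (h in hdr_idx) {
    if (!nzchar(trimws(sub("^>", "", lines[h]))))
      stop("malformed FASTA at line ", h, ": empty header", call. = FALSE)
    nxt <- lines[seq_len(length(lines)) > h]
    upto <- which(startsWith(nxt, ">"))
    body <- if (length(upto)) nxt[seq_len(upto[1] - 1)] else nxt
    if (!any(nzchar(trimws(body))))
      stop("malformed FASTA at line ", h, ": header '",
           sub("^>", "", lines[h]), "' has no sequence", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write protein records to a FASTA file
#'
#' @param records data frame with columns `id`, `residues` and optionally
#'   `description` (as returned by [read_fasta()] or [generate_synthetic()]).
#' @param path output file path.
#' @param width line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  set <- Biostrings::BStringSet(records$residues)
  desc <- records$description
  names(set) <- if (!is.null(desc) && any(nzchar(desc)))
    ifelse(nzchar(desc), paste(records$id, desc), records$id) else records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Remove exact duplicate sequences
#'
#' Keeps, among records with byte-identical residue strings, only the first in
#' input order — the redundancy-removal step usually done with CD-HIT at a
#' 100% identity threshold.
#'
#' @param records data frame with a `residues` column.
#' @return A list with `kept` (the de-duplicated records, input order
#'   preserved) and `removed_count`.
#' @export
dedup_exact <- function(records) {
  dup <- duplicated(records$residues)
  kept <- records[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed_count = sum(dup))
}

#' Parse an EC label string
#'
#' Accepts `"non_enzyme"`, a main class `"X"` (X in 1..6), or a sub-class
#' `"X.Y"` whose prefix is the main class. Only the first two positions of
#' the EC hierarchy are modeled.
#'
#' @param x a single label string.
#' @return A list with `non_enzyme` (logical), `main_class` (integer or NA)
#'   and `sub_class` (string or NA).
#' @export
parse_ec_label <- function(x) {
  stopifnot(length(x) == 1L, is.character(x))
  if (x == "non_enzyme")
    return(list(non_enzyme = TRUE, main_class = NA_integer_,
                sub_class = NA_character_))
  if (grepl("^[0-9]+$", x)) {
    main <- as.integer(x)
    if (main < 1L || main > 6L)
      stop("EC main class out of range 1-6: '", x, "'", call. = FALSE)
    return(list(non_enzyme = FALSE, main_class = main,
                sub_class = NA_character_))
  }
  if (!grepl("^[0-9]+\\.[0-9]+$", x))
    stop("unparseable label: '", x, "'", call. = FALSE)
  main <- as.integer(sub("\\..*$", "", x))
  if (main < 1L || main > 6L)
    stop("EC main class out of range 1-6: '", x, "'", call. = FALSE)
  list(non_enzyme = FALSE, main_class = main, sub_class = x)
}

#' Read a label file
#'
#' Two-column tab-separated file, no header: sequence id and label
#' (`non_enzyme`, a main class `"X"`, or a sub-class `"X.Y"`). Every label is
#' validated with [parse_ec_label()].
#'
#' @param path path to the TSV.
#' @return A named character vector mapping id to label string.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(tab) != 2L)
    stop("label file must have exactly two tab-separated columns",
         call. = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("duplicate id(s) in label file: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "),
         call. = FALSE)
  for (lab in unique(tab[[2]])) parse_ec_label(lab)
  setNames(tab[[2]], tab[[1]])
}

#' @rdname read_labels
#' @param labels named character vector (id -> label).
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(names(labels), unname(labels)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# label helpers used across modules
label_main_class <- function(labels) {
  out <- rep(NA_integer_, length(labels))
  enz <- !is.na(labels) & labels != "non_enzyme"
  out[enz] <- as.integer(sub("\\..*$", "", labels[enz]))
  out
}
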