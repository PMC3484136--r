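#' Hairpin record
#'
#' Container for one candidate precursor: RNA sequence, dot-bracket secondary
#' structure, minimum free energy (kcal/mol) and, for annotated training
#' records, the mature miRNA interval(s).
#'
#' @param id single character identifier.
#' @param sequence RNA string over A/C/G/U. `T` is accepted on input and
#'   normalized to `U`; any other letter (including ambiguity codes) is a
#'   validation error because the stem-bulge-gap pair classes are only
#'   defined for CG, AU and GU pairs.
#' @param dotbracket balanced dot-bracket string of the same length as
#'   `sequence`.
#' @param mfe minimum free energy in kcal/mol (<= 0 for folded structures,
#'   0 for an open chain). `NA` when unknown.
#' @param mature `NULL`, or a data frame with columns `start`, `end`
#'   (1-based inclusive precursor coordinates) and `arm` (`"5p"` or `"3p"`);
#'   at most one row per arm.
#' @return An object of class `"hairpin_record"`.
#' @examples
#' hairpin_record("h1", "GGGGAAAACCCC", "((((....))))", mfe = -6)
#' @export
hairpin_record <- function(id, sequence, dotbracket, mfe = NA_real_, mature = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_rna(sequence, what = id)
  if (!is.character(dotbracket) || length(dotbracket) != 1L)
    stop("dotbracket must be a single string")
  if (nchar(dotbracket) != nchar(sequence))
    stop(sprintf("record '%s': structure length %d != sequence length %d",
                 id, nchar(dotbracket), nchar(sequence)))
  parse_pairs(dotbracket)  # validates characters and balance
  n <- nchar(sequence)
  if (!is.null(mature)) {
    mature <- as.data.frame(mature, stringsAsFactors = FALSE)
    need <- c("start", "end", "arm")
    if (!all(need %in% names(mature)))
      stop("mature annotation needs columns start, end, arm")
    if (!all(mature$arm %in% c("5p", "3p")))
      stop("mature arm labels must be '5p' or '3p'")
    if (anyDuplicated(mature$arm))
      stop(sprintf("record '%s': more than one mature interval per arm", id))
    bad <- mature$start < 1L | mature$end > n | mature$start > mature$end
    if (any(bad))
      stop(sprintf("record '%s': mature interval outside [1, %d] or start > end", id, n))
  }
  structure(list(id = id, sequence = sequence, dotbracket = dotbracket,
                 mfe = as.numeric(mfe), mature = mature),
            class = "hairpin_record")
}

#' @export
print.hairpin_record <- function(x, ...) {
  cat(sprintf("<hairpin_record> %s (%d nt, MFE %s kcal/mol)\n", x$id,
              nchar(x$sequence),
              if (is.na(x$mfe)) "NA" else format(x$mfe)))
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n")
  if (!is.null(x$mature))
    for (r in seq_len(nrow(x$mature)))
      cat(sprintf("  mature %s: %d-%d\n", x$mature$arm[r],
                  x$mature$start[r], x$mature$end[r]))
  invisible(x)
}

# uppercase, T -> U, reject anything outside ACGU
normalize_rna <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s)) {
    bad <- unique(strsplit(gsub("[ACGU]", "", s), "")[[1]])
    stop(sprintf("'%s': invalid residue(s) %s (only A/C/G/U, with T read as U)",
                 what, paste(bad, collapse = ", ")))
  }
  s
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that additionally
#' enforces RNA normalization (uppercase, `T` to `U`) and rejects empty
#' records with a line-numbered error.
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s: empty file", path))
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop(sprintf("%s: line 1: expected FASTA header ('>')", path))
  blank <- !nzchar(trimws(lines))
  for (h in which(hdr)) {
    if (!nzchar(trimws(sub("^>", "", lines[h]))))
      stop(sprintf("%s: line %d: malformed FASTA header", path, h))
    nxt <- h + 1L
    while (nxt <= length(lines) && blank[nxt]) nxt <- nxt + 1L
    if (nxt > length(lines) || hdr[nxt])
      stop(sprintf("%s: line %d: record with empty sequence", path, h))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- vapply(seq_along(set), function(i)
    normalize_rna(as.character(set[[i]]), what = ids[i]), character(1))
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records a data frame with columns `id` and `sequence`, or a list of
#'   [hairpin_record()] objects.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  if (is.data.frame(records)) {
    ids <- records$id; seqs <- records$sequence
  } else {
    ids <- vapply(records, `[[`, character(1), "id")
    seqs <- vapply(records, `[[`, character(1), "sequence")
  }
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.vienna_struct_re <- "^([.()]+)[ \t]*\\([ \t]*(-?[0-9]+(\\.[0-9]+)?)[ \t]*\\)[ \t]*$"

#' Read hairpin records from a Vienna (RNAfold-style) file
#'
#' Expects triples of lines: a `>` header, the sequence, and the dot-bracket
#' structure followed by the minimum free energy in parentheses, e.g.
#' `((((....)))) (-5.20)`. Whitespace inside the parentheses is tolerated.
#'
#' @param path path to a Vienna-format file.
#' @return list of [hairpin_record()] objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3L != 0L)
    stop(sprintf("%s: expected header/sequence/structure triples", path))
  out <- vector("list", length(lines) %/% 3L)
  for (r in seq_along(out)) {
    i <- 3L * (r - 1L) + 1L
    if (!grepl("^>", lines[i]))
      stop(sprintf("%s: record %d: expected '>' header, got '%s'", path, r, lines[i]))
    id <- sub("\\s.*$", "", sub("^>", "", lines[i]))
    m <- regmatches(lines[i + 2L], regexec(.vienna_struct_re, lines[i + 2L]))[[1]]
    if (!length(m))
      stop(sprintf("%s: record %d ('%s'): cannot parse structure/MFE line", path, r, id))
    out[[r]] <- hairpin_record(id, lines[i + 1L], m[2], mfe = as.numeric(m[3]))
  }
  out
}

#' Write hairpin records in Vienna format
#'
#' Inverse of [read_vienna()]: `read_vienna(write_vienna(x, f))` reproduces
#' `x` (MFE printed with two decimals).
#'
#' @param records list of [hairpin_record()] objects.
#' @param path output path.
#' @export
write_vienna <- function(records, path) {
  if (inherits(records, "hairpin_record")) records <- list(records)
  lines <- unlist(lapply(records, function(h) {
    mfe <- if (is.na(h$mfe)) 0 else h$mfe
    c(paste0(">", h$id), h$sequence,
      sprintf("%s (%.2f)", h$dotbracket, mfe))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Fold an RNA sequence with an external MFE engine
#'
#' Adapter around a command-line minimum-free-energy folder (RNAfold by
#' default). Folding is optional throughout the package: every other function
#' accepts dot-bracket structures directly, and this adapter fails with an
#' explicit message when the engine is not on the PATH. Engine defaults
#' (temperature, dangles) are used as shipped; the engine name is recorded in
#' the result so runs are traceable.
#'
#' @param sequence RNA string (T accepted, mapped to U).
#' @param engine name of the folding executable.
#' @return list with `dotbracket`, `mfe` (kcal/mol, 0 for an open chain) and
#'   `engine`.
#' @export
fold_sequence <- function(sequence, engine = "RNAfold") {
  sequence <- normalize_rna(sequence)
  if (!nchar(sequence)) stop("cannot fold an empty sequence")
  if (Sys.which(engine) == "")
    stop(sprintf(paste0("folding engine '%s' not found on PATH; folding is ",
                        "optional -- supply dot-bracket structures instead ",
                        "(e.g. via read_vienna())"), engine))
  out <- suppressWarnings(system2(engine, "--noPS", input = sequence, stdout = TRUE))
  m <- regmatches(out, regexec(.vienna_struct_re, out))
  hit <- which(vapply(m, length, 0L) > 0L)
  if (!length(hit)) stop(sprintf("could not parse output of '%s'", engine))
  db <- m[[hit[1]]][2]; mfe <- as.numeric(m[[hit[1]]][3])
  if (nchar(db) != nchar(sequence))
    stop(sprintf("engine returned structure of length %d for %d nt input",
                 nchar(db), nchar(sequence)))
  parse_pairs(db)
  list(dotbracket = db, mfe = mfe, engine = engine)
}

#' Read a mature-miRNA annotation table
#'
#' Tab-separated text with a header row and columns `precursor_id`, `start`,
#' `end` (1-based inclusive, precursor coordinates) and `arm` (`5p`/`3p`).
#'
#' @param path path to the annotation TSV.
#' @return data frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("precursor_id", "start", "end", "arm")
  if (!all(need %in% names(ann)))
    stop(sprintf("%s: annotation table needs columns %s", path,
                 paste(need, collapse = ", ")))
  if (!all(ann$arm %in% c("5p", "3p")))
    stop(sprintf("%s: arm labels must be '5p' or '3p'", path))
  ann
}

#' @rdname read_annotations
#' @param ann annotation data frame as returned by [read_annotations()].
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach mature annotations to hairpin records
#'
#' @param records list of [hairpin_record()] objects.
#' @param ann annotation data frame (see [read_annotations()]).
#' @return the records, with matching `mature` intervals filled in.
#' @export
attach_annotations <- function(records, ann) {
  lapply(records, function(h) {
    rows <- ann[ann$precursor_id == h$id, , drop = FALSE]
    if (!nrow(rows)) return(h)
    hairpin_record(h$id, h$sequence, h$dotbracket, h$mfe,
                   mature = rows[, c("start", "end", "arm")])
  })
}
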