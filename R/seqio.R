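#' Read a FASTA file
#'
#' Parses a plain multi-record FASTA file into a sequence set.  Sequence
#' lines belonging to one header are concatenated and uppercased.  For DNA,
#' IUPAC ambiguity codes other than N (R, Y, S, W, K, M, B, D, H, V) are
#' normalised to N, so downstream code sees the five-letter alphabet ACGTN.
#' Protein records may use the 20 standard residues plus X and `*`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @param allow_gaps permit `-` and `.` characters (used by
#'   [read_aligned_fasta()]); they are preserved verbatim.
#' @return a `data.frame` with columns `id`, `description`, `residues` and
#'   attribute `alphabet`; one row per record, input order preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a toy record", "MK", "T"), tf)
#' read_fasta(tf, "protein")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein"),
                       allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  ids <- character(0); descs <- character(0); seqs <- character(0)
  cur <- NULL          # growing residue chunks of the current record
  cur_line <- 0L       # header line number of the current record

  flush_record <- function(at_line) {
    if (is.null(cur)) return(invisible())
    res <- paste(cur, collapse = "")
    if (!nzchar(res))
      stop("FASTA parse error at line ", cur_line,
           ": record '", ids[length(ids)], "' has an empty sequence")
    seqs[length(seqs) + 1L] <<- res
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush_record(i)
      hdr <- sub("^>", "", ln)
      tok <- regmatches(hdr, regexpr("^\\S+", hdr))
      if (length(tok) == 0L || !nzchar(tok))
        stop("FASTA parse error at line ", i, ": empty record id")
      ids <- c(ids, tok)
      descs <- c(descs, trimws(sub("^\\S+", "", hdr)))
      cur <- character(0)
      cur_line <- i
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur))
        stop("FASTA parse error at line ", i,
             ": sequence data before the first header")
      chunk <- toupper(gsub("\\s", "", ln))
      bad <- check_alphabet(chunk, alphabet, allow_gaps)
      if (!is.na(bad))
        stop("FASTA parse error at line ", i, ": illegal ", alphabet,
             " character '", bad, "'")
      if (alphabet == "dna") chunk <- normalize_ambiguity(chunk)
      cur <- c(cur, chunk)
    }
  }
  flush_record(length(lines) + 1L)

  out <- data.frame(id = ids, description = descs, residues = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

# Returns NA if all characters are legal, otherwise the first offender.
check_alphabet <- function(chunk, alphabet, allow_gaps = FALSE) {
  legal <- if (alphabet == "dna") "ACGTNRYSWKMBDHV" else
    paste0(paste(AA_ALPHABET, collapse = ""), "X*")
  if (allow_gaps) legal <- paste0(legal, "-.")
  pat <- paste0("[^", gsub("([.*])", "\\\\\\1", legal), "]")
  m <- regmatches(chunk, regexpr(pat, chunk))
  if (length(m) == 0L) NA_character_ else m
}

normalize_ambiguity <- function(x) chartr("RYSWKMBDHV", "NNNNNNNNNN", x)

new_seq_set <- function(id, residues, description = "", alphabet) {
  out <- data.frame(id = id, description = description, residues = residues,
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequences to a FASTA file
#'
#' @param records a sequence set as returned by [read_fasta()] (columns
#'   `id`, `description`, `residues`).
#' @param path output path.
#' @param line_width residues per line (positive integer).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- records$description[i]
    hdr <- if (!is.null(desc) && nzchar(desc))
      paste0(">", records$id[i], " ", desc) else paste0(">", records$id[i])
    writeLines(hdr, con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Reverse complement of DNA records
#'
#' A<->T, C<->G, N<->N, order reversed.  Applying it twice is the identity.
#'
#' @param dna a DNA sequence set (attribute `alphabet == "dna"`).
#' @return a sequence set of the same shape.
#' @export
reverse_complement <- function(dna) {
  if (!identical(attr(dna, "alphabet"), "dna"))
    stop("reverse_complement() requires a DNA sequence set")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(dna$residues)))
  new_seq_set(dna$id, unname(rc), dna$description, "dna")
}

#' Translate one reading frame
#'
#' Translates each contig in a single frame with the standard genetic code
#' (NCBI table 1).  Stop codons split the frame into maximal stop-free
#' segments; segments shorter than `min_peptide_len` are dropped.  Codons
#' containing N translate to X.  Coordinates are 1-based, inclusive, on the
#' forward strand of the source contig, so `nt_end - nt_start + 1` is
#' always three times the peptide length, for negative frames too.
#'
#' @param dna a DNA sequence set.
#' @param frame an integer in `{+1,+2,+3,-1,-2,-3}`; negative frames read
#'   the reverse complement with offset `|frame| - 1`.
#' @param min_peptide_len minimum segment length in residues (default 20).
#' @return a `data.frame` with columns `contig_id`, `frame`,
#'   `segment_index`, `peptide`, `nt_start`, `nt_end`.  `segment_index`
#'   numbers all stop-delimited segments of the frame, before the length
#'   filter, so indices do not shift when the filter changes.
#' @export
translate_frame <- function(dna, frame, min_peptide_len = 20L) {
  if (!(length(frame) == 1L && frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)))
    stop("frame must be one of +1,+2,+3,-1,-2,-3")
  if (!identical(attr(dna, "alphabet"), "dna"))
    stop("translate_frame() requires a DNA sequence set")
  code <- Biostrings::GENETIC_CODE
  out <- vector("list", nrow(dna))
  for (i in seq_len(nrow(dna))) {
    s <- dna$residues[i]
    L <- nchar(s)
    work <- if (frame > 0) s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    off <- abs(frame) - 1L
    ncod <- (L - off) %/% 3L
    if (ncod < 1L) next
    cs <- off + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(work, cs, cs + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"                      # codon contains N
    segs <- split_segments(aa)
    if (nrow(segs) == 0L) next
    keep <- segs$len >= min_peptide_len
    segs <- segs[keep, , drop = FALSE]
    if (nrow(segs) == 0L) next
    # working-strand nt interval of each segment
    ws <- off + 3L * (segs$from - 1L) + 1L
    we <- off + 3L * segs$to
    if (frame > 0) { ns <- ws; ne <- we } else { ns <- L - we + 1L; ne <- L - ws + 1L }
    out[[i]] <- data.frame(
      contig_id = dna$id[i], frame = frame, segment_index = segs$index,
      peptide = segs$pep, nt_start = ns, nt_end = ne,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(contig_id = character(0), frame = integer(0),
                      segment_index = integer(0), peptide = character(0),
                      nt_start = integer(0), nt_end = integer(0)))
  do.call(rbind, out)
}

# Maximal runs of non-stop residues in a translated frame, with codon
# coordinates and an index over all runs (pre length filter).
split_segments <- function(aa) {
  is_stop <- aa == "*"
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  open <- !r$values
  from <- starts[open]; to <- ends[open]
  if (length(from) == 0L)
    return(data.frame(index = integer(0), from = integer(0), to = integer(0),
                      len = integer(0), pep = character(0)))
  pep <- vapply(seq_along(from), function(j)
    paste(aa[from[j]:to[j]], collapse = ""), character(1))
  data.frame(index = seq_along(from), from = from, to = to,
             len = to - from + 1L, pep = pep, stringsAsFactors = FALSE)
}

#' Six-frame translation
#'
#' Union of [translate_frame()] over frames +1, +2, +3, -1, -2, -3, ordered
#' by contig, frame, then segment index.  Each row's `target_id` encodes
#' provenance as `<contig>|frame=<f>|seg=<k>|<start>-<end>`.
#'
#' @inheritParams translate_frame
#' @return a `data.frame` of translated segments (see [translate_frame()])
#'   with an extra `target_id` column.
#' @export
six_frame_translate <- function(dna, min_peptide_len = 20L) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  res <- do.call(rbind, lapply(frames, function(f)
    translate_frame(dna, f, min_peptide_len)))
  ord <- order(match(res$contig_id, dna$id),
               match(res$frame, frames), res$segment_index)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res$target_id <- sprintf("%s|frame=%+d|seg=%d|%d-%d", res$contig_id,
                           res$frame, res$segment_index, res$nt_start,
                           res$nt_end)
  res
}
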