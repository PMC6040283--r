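#' Sequence records
#'
#' A `seq_record` is a light container for one identified nucleotide or
#' protein sequence with provenance. Residues are stored upper-case; on
#' nucleotide input `U` is mapped to `T`.
#'
#' @param id Record identifier (non-empty string).
#' @param residues Sequence string (IUPAC letters; ambiguity codes allowed
#'   for nucleotides, `X` for protein).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description Free-text description (FASTA header remainder).
#' @param source Provenance note (file path or accession).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet = c("nucleotide", "protein"),
                       description = "", source = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("'id' must be a non-empty string")
  }
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  if (alphabet == "nucleotide") {
    residues <- gsub("U", "T", residues, fixed = TRUE)
    bad <- gsub("[ACGTRYSWKMBDHVN-]", "", residues)
  } else {
    bad <- gsub("[ACDEFGHIKLMNPQRSTVWYXBZJUO*-]", "", residues)
  }
  if (nzchar(bad)) {
    stop("record '", id, "': residues not in the ", alphabet,
         " alphabet: ", substr(bad, 1, 10))
  }
  structure(
    list(id = id, alphabet = alphabet, residues = residues,
         description = description, source = source),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %d residues] %s\n", x$id, x$alphabet,
              nchar(x$residues), x$description))
  invisible(x)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] with a structural
#' pre-scan so malformed headers and empty entries are reported with the
#' offending line number. Order is preserved; whitespace inside sequences
#' is stripped and case is normalized to upper.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A list of [seq_record()] objects, one per entry, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1],
         " is not a header (expected '>')")
  }
  hdr <- which(startsWith(trimws(lines), ">"))
  for (k in seq_along(hdr)) {
    if (trimws(lines[hdr[k]]) == ">") {
      stop("malformed FASTA: empty header at line ", hdr[k])
    }
    to <- if (k < length(hdr)) hdr[k + 1] - 1L else length(lines)
    body <- lines[seq(hdr[k] + 1L, length.out = max(0L, to - hdr[k]))]
    if (!any(nzchar(gsub("[[:space:]]", "", body)))) {
      stop("malformed FASTA: empty sequence for header at line ", hdr[k])
    }
  }
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    nm <- names(set)[i]
    id <- sub("[[:space:]].*$", "", nm)
    desc <- sub("^[^[:space:]]+[[:space:]]*", "", nm)
    out[[i]] <- seq_record(id, as.character(set[[i]]), alphabet,
                           description = desc, source = path)
  }
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(out) <- ids
  out
}

#' Write records to FASTA
#'
#' @param records A list of [seq_record()] objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width in columns (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read the sequence from a GenBank flat file
#'
#' Minimal reader: takes the LOCUS name as id and concatenates the ORIGIN
#' block, stripping position digits, spaces and the trailing `//`. Feature
#' tables are ignored.
#'
#' @param path Path to a GenBank flat file.
#' @param alphabet Declared alphabet of the record.
#' @return A single [seq_record()].
#' @export
read_genbank_seq <- function(path, alphabet = "nucleotide") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  loc <- grep("^LOCUS", lines)
  id <- if (length(loc)) strsplit(trimws(lines[loc[1]]), "[[:space:]]+")[[1]][2]
        else basename(path)
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("not a GenBank flat file (no ORIGIN block): ", path)
  end <- grep("^//", lines)
  end <- if (length(end)) min(end[end > ori[1]]) else length(lines) + 1L
  body <- lines[seq(ori[1] + 1L, length.out = max(0L, end - ori[1] - 1L))]
  seq <- gsub("[0-9[:space:]/]", "", paste(body, collapse = ""))
  if (!nzchar(seq)) stop("empty ORIGIN block in ", path)
  seq_record(id, seq, alphabet, source = path)
}

#' Fetch a GenBank record from NCBI
#'
#' Downloads a flat file through NCBI efetch. Network access is required;
#' the test suite never calls this and works from packaged or generated
#' fixtures instead.
#'
#' @param accession Accession string (e.g. `"KC306394"`).
#' @param dest Destination path (default: tempfile).
#' @return The path of the downloaded flat file.
#' @export
fetch_genbank <- function(accession, dest = tempfile(fileext = ".gb")) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=gb&retmode=text&id=", accession)
  utils::download.file(url, dest, quiet = TRUE)
  dest
}

#' Translate a coding sequence
#'
#' Standard genetic code, one letter per codon. A trailing stop codon is
#' dropped; an internal stop is an error (its codon index is reported).
#' With `strict = TRUE` the sequence must begin with ATG; with
#' `strict = FALSE` the bacterial alternative starts GTG and TTG are also
#' accepted and rendered as the initiator Met.
#'
#' @param orf_nt Nucleotide string, length divisible by 3.
#' @param strict Require an ATG start codon (default `TRUE`).
#' @return The protein string.
#' @export
translate_orf <- function(orf_nt, strict = TRUE) {
  s <- toupper(gsub("[[:space:]]", "", orf_nt))
  s <- gsub("U", "T", s, fixed = TRUE)
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a multiple of 3")
  }
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  start <- codons[1]
  if (strict && start != "ATG") {
    stop("strict mode: sequence does not start with ATG (saw ", start, ")")
  }
  if (!strict && !start %in% c("ATG", "GTG", "TTG")) {
    stop("sequence does not start with a start codon (ATG/GTG/TTG; saw ",
         start, ")")
  }
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) {
    stop("untranslatable codon '", codons[which(is.na(aa))[1]],
         "' at codon ", which(is.na(aa))[1])
  }
  aa[1] <- "M"  # initiator is Met even for GTG/TTG starts
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  stops <- which(aa == "*")
  if (length(stops)) {
    stop("internal stop codon at codon ", stops[1])
  }
  paste(aa, collapse = "")
}

revcomp <- function(nt) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

#' Find open reading frames
#'
#' Scans both strands for ORFs running from an ATG to the next in-frame
#' stop codon (stop included) and returns those with nucleotide length at
#' least `min_len_nt`, sorted by descending length. Coordinates are 1-based
#' and inclusive on the forward strand of the parent; for `-` strand ORFs
#' the reading direction runs from `end` down to `start` (the last base of
#' the stop codon sits at `start`).
#'
#' @param seq A nucleotide [seq_record()].
#' @param min_len_nt Minimum ORF length in nucleotides, stop included.
#' @return A data.frame with columns `parent_id`, `start`, `end`, `strand`,
#'   `protein` (one row per ORF); zero rows when none are found.
#' @export
find_orfs <- function(seq, min_len_nt = 90L) {
  stopifnot(inherits(seq, "seq_record"))
  if (seq$alphabet != "nucleotide") stop("find_orfs needs a nucleotide record")
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    res <- list()
    for (frame in 0:2) {
      starts <- seq(1L + frame, n - 2L, by = 3L)
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      stop_idx <- which(is_stop)
      for (i in which(is_start)) {
        nxt <- stop_idx[stop_idx > i]
        if (!length(nxt)) next
        j <- nxt[1]
        len <- (j - i + 1L) * 3L
        if (len < min_len_nt) next
        orf_nt <- substr(s, starts[i], starts[j] + 2L)
        if (strand == "+") {
          st <- starts[i]; en <- starts[j] + 2L
        } else {
          # positions on the forward strand: reverse-complement mapping
          st <- n - (starts[j] + 2L) + 1L
          en <- n - starts[i] + 1L
        }
        res[[length(res) + 1L]] <- data.frame(
          parent_id = seq$id, start = st, end = en, strand = strand,
          protein = translate_orf(orf_nt), stringsAsFactors = FALSE)
      }
    }
    res
  }
  fwd <- scan_strand(seq$residues, "+")
  rev <- scan_strand(revcomp(seq$residues), "-")
  out <- do.call(rbind, c(fwd, rev))
  if (is.null(out)) {
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(-(out$end - out$start + 1L), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim an annotated signal peptide
#'
#' The cleavage site is a user-supplied annotation (e.g. from an external
#' predictor); no prediction is performed here.
#'
#' @param precursor Protein string (the full translated chain).
#' @param cleavage_after 1-based index of the last signal-peptide residue;
#'   must satisfy `0 < cleavage_after < nchar(precursor)`.
#' @param precursor_id Optional id carried into the result.
#' @return A list of class `mature_chain` with `precursor_id`,
#'   `cleavage_after` and `mature`.
#' @export
trim_signal_peptide <- function(precursor, cleavage_after,
                                precursor_id = "") {
  n <- nchar(precursor)
  if (!is.numeric(cleavage_after) || length(cleavage_after) != 1L ||
      cleavage_after != as.integer(cleavage_after) ||
      cleavage_after <= 0L || cleavage_after >= n) {
    stop("cleavage_after must be an integer in (0, ", n, ")")
  }
  structure(
    list(precursor_id = precursor_id,
         cleavage_after = as.integer(cleavage_after),
         mature = substr(precursor, cleavage_after + 1L, n)),
    class = "mature_chain"
  )
}
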