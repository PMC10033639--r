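## Guide quantification: sgRNA amplicon FASTQ -> raw guide x sample
## count matrix, via exact barcode demultiplexing and exact (optionally
## 1-mismatch) protospacer matching downstream of a fixed anchor.

#' Validate a guide library table
#'
#' @param lib Data frame with columns \code{guide_id}, \code{gene},
#'   \code{protospacer}, \code{is_ntc}.
#' @return The validated library (invisibly usable downstream).
#' @export
validate_guide_library <- function(lib) {
  need <- c("guide_id", "gene", "protospacer", "is_ntc")
  if (!is.data.frame(lib) || !all(need %in% names(lib))) {
    stop("guide library needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lib$guide_id)) {
    stop("guide_ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(lib$protospacer)) {
    stop("protospacers must be unique", call. = FALSE)
  }
  if (any(!grepl("^[ACGT]+$", lib$protospacer))) {
    stop("protospacers must be uppercase DNA (A/C/G/T only)",
         call. = FALSE)
  }
  lib$is_ntc <- as.logical(lib$is_ntc)
  lib
}

#' Validate a sample sheet
#'
#' @param sheet Data frame with columns \code{sample_id},
#'   \code{genotype} (WT or CD8KO), \code{stage} (early, late or
#'   terminal), \code{mouse_id} and \code{barcode}.
#' @return The validated sheet.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "genotype", "stage", "mouse_id", "barcode")
  if (!is.data.frame(sheet) || !all(need %in% names(sheet))) {
    stop("sample sheet needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (anyDuplicated(sheet$barcode)) {
    stop("duplicate barcodes in sample sheet", call. = FALSE)
  }
  if (length(unique(nchar(sheet$barcode))) > 1L) {
    stop("all barcodes must have equal length", call. = FALSE)
  }
  if (!all(sheet$genotype %in% c("WT", "CD8KO"))) {
    stop("genotype must be one of WT, CD8KO", call. = FALSE)
  }
  if (!all(sheet$stage %in% c("early", "late", "terminal"))) {
    stop("stage must be one of early, late, terminal", call. = FALSE)
  }
  sheet
}

#' Read sequences from a FASTQ file
#'
#' Plain or gzip-compressed 4-line FASTQ; base qualities are ignored
#' (matching is sequence-only).
#'
#' @param path FASTQ file path.
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Demultiplex reads by in-read sample barcode
#'
#' Each read is assigned to exactly one sample by exact match of the
#' barcode found at a fixed offset in the read; reads whose barcode
#' matches no sheet entry are counted as unassigned.
#'
#' @param reads Character vector of read sequences.
#' @param sheet Sample sheet (see \code{\link{validate_sample_sheet}}).
#' @param barcode_start 1-based offset of the barcode within the read
#'   (default 1: barcode at the read start).
#' @return List with \code{reads} (named list of per-sample character
#'   vectors, in sheet order) and \code{unassigned} (read count).
#' @export
demultiplex <- function(reads, sheet, barcode_start = 1L) {
  sheet <- validate_sample_sheet(sheet)
  bl <- nchar(sheet$barcode[1])
  bc <- substr(reads, barcode_start, barcode_start + bl - 1L)
  idx <- match(bc, sheet$barcode)
  out <- lapply(seq_len(nrow(sheet)),
                function(j) reads[!is.na(idx) & idx == j])
  names(out) <- sheet$sample_id
  list(reads = out, unassigned = sum(is.na(idx)))
}

## 1-mismatch lookup: every Hamming-1 neighbor of every protospacer,
## with neighbors claimed by more than one guide marked ambiguous.
hamming1_lookup <- function(protospacers) {
  k <- nchar(protospacers[1])
  bases <- c("A", "C", "G", "T")
  neigh <- lapply(seq_along(protospacers), function(i) {
    p <- protospacers[i]
    unlist(lapply(seq_len(k), function(pos) {
      cur <- substr(p, pos, pos)
      vapply(setdiff(bases, cur), function(b) {
        paste0(substr(p, 1, pos - 1L), b, substr(p, pos + 1L, k))
      }, character(1))
    }), use.names = FALSE)
  })
  key <- unlist(neigh, use.names = FALSE)
  guide <- rep(seq_along(protospacers),
               vapply(neigh, length, integer(1)))
  dup <- key[duplicated(key)]
  ambiguous <- unique(dup)
  keep <- !(key %in% ambiguous) & !(key %in% protospacers)
  list(key = key[keep], guide = guide[keep])
}

#' Count guides in per-sample read sets
#'
#' A read increments guide g when the 20-mer immediately following the
#' first occurrence of \code{anchor} (or at the fixed offset
#' \code{proto_start} when no anchor is given) exactly equals g's
#' protospacer. Reads with no extractable 20-mer are tallied as skipped;
#' extractable 20-mers matching no guide as unassigned. With
#' \code{max_mismatch = 1}, a 20-mer at Hamming distance 1 from exactly
#' one protospacer also counts; hits ambiguous between guides are
#' discarded as unassigned.
#'
#' @param reads_by_sample Named list of per-sample read vectors, e.g.
#'   from \code{\link{demultiplex}}.
#' @param lib Guide library.
#' @param anchor DNA string directly 5' of the protospacer; set to
#'   \code{NULL} to use \code{proto_start} instead.
#' @param proto_start 1-based protospacer offset used when
#'   \code{anchor} is \code{NULL}.
#' @param max_mismatch 0 (default, exact) or 1.
#' @return List with \code{counts} (integer guide x sample matrix) and
#'   \code{tallies} (per-sample assigned / unassigned / skipped counts).
#' @export
count_guides <- function(reads_by_sample, lib, anchor = NULL,
                         proto_start = NULL, max_mismatch = 0L) {
  lib <- validate_guide_library(lib)
  if (is.null(anchor) && is.null(proto_start)) {
    stop("provide either `anchor` or `proto_start`", call. = FALSE)
  }
  if (!is.null(anchor) && (!is.character(anchor) || !nzchar(anchor))) {
    stop("`anchor` must be a nonempty DNA string", call. = FALSE)
  }
  if (!max_mismatch %in% c(0L, 1L)) {
    stop("`max_mismatch` must be 0 or 1", call. = FALSE)
  }
  lut1 <- if (max_mismatch == 1L) hamming1_lookup(lib$protospacer)

  samples <- names(reads_by_sample)
  counts <- matrix(0L, nrow = nrow(lib), ncol = length(samples),
                   dimnames = list(lib$guide_id, samples))
  tallies <- data.frame(sample_id = samples, assigned = 0L,
                        unassigned = 0L, skipped = 0L,
                        stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    reads <- reads_by_sample[[j]]
    n <- length(reads)
    if (n == 0L) next
    if (!is.null(anchor)) {
      pos <- regexpr(anchor, reads, fixed = TRUE)
      start <- ifelse(pos > 0L, pos + nchar(anchor), NA_integer_)
    } else {
      start <- rep(as.integer(proto_start), n)
    }
    ok <- !is.na(start) & nchar(reads) >= start + 19L
    mer <- rep(NA_character_, n)
    mer[ok] <- substr(reads[ok], start[ok], start[ok] + 19L)
    hit <- match(mer, lib$protospacer)
    if (max_mismatch == 1L) {
      miss <- ok & is.na(hit)
      hit[miss] <- lut1$guide[match(mer[miss], lut1$key)]
    }
    assigned <- !is.na(hit)
    tab <- tabulate(hit[assigned], nbins = nrow(lib))
    counts[, j] <- as.integer(tab)
    tallies$assigned[j] <- sum(assigned)
    tallies$skipped[j] <- sum(!ok)
    tallies$unassigned[j] <- sum(ok & !assigned)
  }
  list(counts = counts, tallies = tallies)
}

#' Quantify a screen from one multiplexed FASTQ
#'
#' Convenience wrapper: read FASTQ, demultiplex by in-read barcode, then
#' count protospacers downstream of the anchor.
#'
#' @inheritParams demultiplex
#' @inheritParams count_guides
#' @param fastq Path to the multiplexed FASTQ file.
#' @return As \code{\link{count_guides}}, plus
#'   \code{barcode_unassigned}: reads matching no sample barcode.
#' @export
quantify_screen <- function(fastq, lib, sheet, anchor,
                            barcode_start = 1L, max_mismatch = 0L) {
  reads <- read_fastq_seqs(fastq)
  dm <- demultiplex(reads, sheet, barcode_start = barcode_start)
  res <- count_guides(dm$reads, lib, anchor = anchor,
                      max_mismatch = max_mismatch)
  res$barcode_unassigned <- dm$unassigned
  res
}

#' Emit a synthetic multiplexed amplicon FASTQ from a count matrix
#'
#' Writes, for every (guide, sample) cell of \code{counts}, that many
#' reads of the form barcode + anchor + protospacer + A-filler. Inverse
#' of \code{\link{quantify_screen}}: counting the emitted FASTQ with the
#' same anchor reproduces \code{counts} exactly.
#'
#' @param counts Integer guide x sample matrix (rownames = guide_ids,
#'   colnames = sample_ids).
#' @param lib Guide library.
#' @param sheet Sample sheet.
#' @param path Output FASTQ path (plain text).
#' @param anchor Anchor sequence placed directly 5' of the protospacer.
#' @param read_length Total read length; reads are A-padded to it.
#' @return \code{path}, invisibly.
#' @export
write_synthetic_fastq <- function(counts, lib, sheet, path,
                                  anchor = "TTGTGGAAAGGACGAAACACCG",
                                  read_length = 60L) {
  lib <- validate_guide_library(lib)
  sheet <- validate_sample_sheet(sheet)
  stopifnot(identical(rownames(counts), lib$guide_id),
            identical(colnames(counts), sheet$sample_id))
  con <- file(path, open = "wt")
  on.exit(close(con))
  rid <- 0L
  for (j in seq_len(ncol(counts))) {
    nz <- which(counts[, j] > 0L)
    if (length(nz) == 0L) next
    seqs <- paste0(sheet$barcode[j], anchor, lib$protospacer[nz])
    pad <- pmax(0L, read_length - nchar(seqs))
    seqs <- paste0(seqs, strrep("A", pad))
    seqs <- rep(seqs, counts[nz, j])
    ids <- sprintf("@read%08d", rid + seq_along(seqs))
    rid <- rid + length(seqs)
    writeLines(rbind(ids, seqs, "+", strrep("I", nchar(seqs))), con)
  }
  invisible(path)
}
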