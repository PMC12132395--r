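#' Parameters for the longest-ORF scan
#'
#' Mirrors the TransDecoder longest-ORF settings used for transcript coding
#' classification: a minimum protein length of 100 amino acids, sense-strand
#' only ("stranded" mode), and the universal nuclear genetic code. ORFs are
#' ATG-initiated and stop-terminated ("complete") by default; 5'-partial
#' ORFs (a frame-initial stop-free prefix with no ATG requirement) compete
#' only when `allow_5prime_partial = TRUE`.
#'
#' @param min_protein_length Minimum accepted protein length in amino acids.
#' @param stranded If `TRUE` (default) scan the three sense-strand frames
#'   only; if `FALSE`, all six frames on both strands.
#' @param allow_5prime_partial Let a frame-initial stop-free prefix compete
#'   as a partial ORF.
#' @param genetic_code Only `"standard"` (the universal nuclear code) is
#'   supported.
#' @return An object of class `orf_params`.
#' @export
orf_params <- function(min_protein_length = 100L, stranded = TRUE,
                       allow_5prime_partial = FALSE,
                       genetic_code = "standard") {
  min_protein_length <- as.integer(min_protein_length)
  if (is.na(min_protein_length) || min_protein_length < 1L)
    stop("min_protein_length must be an integer >= 1")
  if (!identical(genetic_code, "standard"))
    stop("only the standard (universal nuclear) genetic code is supported")
  structure(list(min_protein_length = min_protein_length,
                 stranded = isTRUE(stranded),
                 allow_5prime_partial = isTRUE(allow_5prime_partial),
                 genetic_code = genetic_code),
            class = "orf_params")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.check_nt <- function(s) {
  if (length(s) != 1L || !is.character(s)) stop("sequence must be a single string")
  s <- toupper(s)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside the A/C/G/T/N alphabet")
  s
}

#' Translate an in-frame nucleotide sequence
#'
#' Standard-code translation. Stop codons translate to `*`; any codon
#' containing `N` translates to `X`.
#'
#' @param codons A nucleotide string whose length is divisible by 3.
#' @return An amino-acid string.
#' @export
translate_codons <- function(codons) {
  s <- .check_nt(codons)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length must be divisible by 3")
  if (n == 0L) return("")
  cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Enumerate candidate ORFs on one strand. Returns a data frame of
# (frame, codon_start, codon_len, nt_start, nt_end, complete); coordinates
# are 1-based on the scanned strand, nt_end includes the stop codon for
# complete ORFs.
.orf_candidates <- function(s, params) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    starts_nt <- f + (seq_len(ncod) - 1L) * 3L + 1L
    cod <- substring(s, starts_nt, starts_nt + 2L)
    stops <- which(cod %in% .STOP_CODONS)
    atg <- which(cod == "ATG")
    if (length(atg) && length(stops)) {
      k <- findInterval(atg, stops) + 1L
      ok <- k <= length(stops)
      if (any(ok)) {
        a <- atg[ok]; st <- stops[k[ok]]
        out[[length(out) + 1L]] <- data.frame(
          frame = f, codon_start = a, codon_len = st - a,
          nt_start = f + (a - 1L) * 3L + 1L, nt_end = f + st * 3L,
          complete = TRUE)
      }
    }
    if (params$allow_5prime_partial) {
      plen <- if (length(stops)) stops[[1L]] - 1L else ncod
      if (plen >= 1L)
        out[[length(out) + 1L]] <- data.frame(
          frame = f, codon_start = 1L, codon_len = plen,
          nt_start = f + 1L, nt_end = f + plen * 3L, complete = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), codon_start = integer(0),
                      codon_len = integer(0), nt_start = integer(0),
                      nt_end = integer(0), complete = logical(0)))
  do.call(rbind, out)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Find the single longest open reading frame of a transcript
#'
#' Scans the three sense-strand frames (six frames across both strands when
#' `stranded = FALSE`) for ATG-initiated, stop-terminated ORFs and returns
#' the longest one whose protein reaches `min_protein_length`. Ties are
#' broken deterministically: smaller start coordinate, then lower frame
#' index, then plus strand before minus. Codons containing `N` translate to
#' `X` and never terminate an ORF.
#'
#' @param sequence Nucleotide string over `A/C/G/T/N` (case-insensitive).
#' @param params An [orf_params()] object.
#' @return `NULL` when no ORF reaches the threshold; otherwise a list (an
#'   "ORF call") with elements `frame` (0/1/2), `strand` (`"+"`/`"-"`;
#'   minus-strand coordinates refer to the reverse complement), `nt_start`,
#'   `nt_end` (1-based inclusive; includes the stop codon iff `complete`),
#'   `length_aa`, `protein` (no `*`), and `complete`.
#' @export
find_longest_orf <- function(sequence, params = orf_params()) {
  s <- .check_nt(sequence)
  cand <- .orf_candidates(s, params)
  cand$strand <- rep("+", nrow(cand))
  if (!params$stranded) {
    rc <- .revcomp(s)
    cand2 <- .orf_candidates(rc, params)
    if (nrow(cand2)) {
      cand2$strand <- "-"
      cand <- rbind(cand, cand2)
    }
  }
  cand <- cand[cand$codon_len >= params$min_protein_length, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  ord <- order(-cand$codon_len, cand$nt_start, cand$frame, cand$strand == "-")
  best <- cand[ord[[1L]], ]
  src <- if (best$strand == "+") s else .revcomp(s)
  cds <- substr(src, best$nt_start, best$nt_start + best$codon_len * 3L - 1L)
  list(frame = best$frame, strand = best$strand,
       nt_start = best$nt_start, nt_end = best$nt_end,
       length_aa = best$codon_len, protein = translate_codons(cds),
       complete = best$complete)
}

.transcript_records <- function(transcripts) {
  if (is.data.frame(transcripts)) {
    id_col <- intersect(c("transcript_id", "protein_id"), names(transcripts))[1]
    if (is.na(id_col) || !"sequence" %in% names(transcripts))
      stop("transcripts must have an ID column and a 'sequence' column")
    stats::setNames(transcripts$sequence, transcripts[[id_col]])
  } else if (is.character(transcripts)) {
    if (length(transcripts) && is.null(names(transcripts)))
      stop("transcript vector must be named by ID")
    transcripts
  } else stop("transcripts must be a record data frame or a named character vector")
}

#' Classify transcripts as protein coding
#'
#' Runs [find_longest_orf()] over a transcript set and keeps exactly the
#' transcripts with an accepted ORF. Deterministic given the input.
#'
#' @param transcripts A data frame from [read_fasta()] (the ID column may be
#'   `protein_id` or `transcript_id`) or a named character vector of
#'   sequences.
#' @param params An [orf_params()] object.
#' @return A data frame of ORF calls with columns `transcript_id`, `frame`,
#'   `strand`, `nt_start`, `nt_end`, `length_aa`, `complete`, `protein`.
#' @export
classify_coding <- function(transcripts, params = orf_params()) {
  seqs <- .transcript_records(transcripts)
  if (anyDuplicated(names(seqs)))
    stop("duplicate transcript ID(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  calls <- lapply(seqs, find_longest_orf, params = params)
  keep <- !vapply(calls, is.null, TRUE)
  ids <- names(seqs)[keep]
  calls <- calls[keep]
  data.frame(
    transcript_id = ids,
    frame = vapply(calls, `[[`, 0L, "frame"),
    strand = vapply(calls, `[[`, "", "strand"),
    nt_start = vapply(calls, `[[`, 0L, "nt_start"),
    nt_end = vapply(calls, `[[`, 0L, "nt_end"),
    length_aa = vapply(calls, `[[`, 0L, "length_aa"),
    complete = vapply(calls, `[[`, TRUE, "complete"),
    protein = vapply(calls, `[[`, "", "protein"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-method transcript summary
#'
#' The per-annotation-method counts behind the coding/orthogroup bar plots:
#' total predicted transcripts, protein-coding transcripts, coding
#' transcripts whose protein sits in at least one orthogroup, and coding
#' transcripts whose protein was not assigned to any orthogroup. Counts are
#' of transcripts (one predicted protein each), and the conservation
#' identity `assigned + unassigned = coding` always holds.
#'
#' @param transcripts Transcript records ([read_fasta()] data frame, or a
#'   character vector of transcript IDs).
#' @param orf_calls Data frame from [classify_coding()].
#' @param table An [orthogroup_table()].
#' @param proteome_id The table column under which this method's proteins
#'   appear.
#' @param method_id Label for the output row (defaults to `proteome_id`).
#' @return One-row data frame: `method_id`, `n_transcripts`, `n_coding`,
#'   `n_coding_in_orthogroups`, `n_unassigned_proteins`.
#' @export
summarize_method <- function(transcripts, orf_calls, table, proteome_id,
                             method_id = proteome_id) {
  ids <- if (is.data.frame(transcripts)) {
    id_col <- intersect(c("transcript_id", "protein_id"), names(transcripts))[1]
    transcripts[[id_col]]
  } else if (!is.null(names(transcripts))) {
    names(transcripts)  # a named vector of sequences
  } else as.character(transcripts)
  if (!proteome_id %in% proteomes(table))
    stop("proteome_id not in the orthogroup table header: ", proteome_id)
  coding <- orf_calls$transcript_id
  stray <- setdiff(coding, ids)
  if (length(stray))
    stop("consistency error: ORF calls for unknown transcript(s): ",
         paste(utils::head(stray, 10L), collapse = ", "))
  in_table <- unique(unlist(lapply(table, `[[`, proteome_id), use.names = FALSE))
  orphans <- setdiff(in_table, coding)
  if (length(orphans))
    stop("consistency error: orthogroup protein(s) with no ORF call: ",
         paste(utils::head(orphans, 10L), collapse = ", "))
  n_assigned <- sum(coding %in% in_table)
  data.frame(method_id = method_id,
             n_transcripts = length(ids),
             n_coding = length(coding),
             n_coding_in_orthogroups = n_assigned,
             n_unassigned_proteins = length(coding) - n_assigned,
             stringsAsFactors = FALSE)
}
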