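#' Read a gene-prediction table
#'
#' Reads the native tab-separated gene-prediction table with one row per
#' predicted gene and the columns \code{GenomeSequence} (name of the genome
#' sequence the gene lies on), \code{Strand} (1 or -1), \code{Left} and
#' \code{Right} (1-based inclusive coordinates, \code{Left <= Right}) and
#' \code{Partial} (logical; \code{TRUE} when the gene runs over the edge of
#' the genome sequence and lacks its start and/or stop codon). This is the
#' common table layout used to store predictions from Prodigal, GeneMark and
#' Glimmer so that they can be compared and merged.
#'
#' @param path path to a tab-separated file with the header above.
#'
#' @return A \code{data.frame} with columns \code{GenomeSequence}
#'   (character), \code{Strand} (integer, +1/-1), \code{Left}, \code{Right}
#'   (integer) and \code{Partial} (logical), one row per prediction.
#'
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("GenomeSequence\tStrand\tLeft\tRight\tPartial",
#'              "seqA\t1\t100\t300\tFALSE"), tf)
#' read_predictions(tf)
#'
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  required <- c("GenomeSequence", "Strand", "Left", "Right", "Partial")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0L)
    stop("prediction table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  parse_int <- function(x, col) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad) > 0L)
      stop("non-integer ", col, " in ", path, " at data line ", bad[1L],
           ": '", x[bad[1L]], "'")
    v
  }
  out <- data.frame(
    GenomeSequence = as.character(tbl$GenomeSequence),
    Strand = parse_int(tbl$Strand, "Strand"),
    Left = parse_int(tbl$Left, "Left"),
    Right = parse_int(tbl$Right, "Right"),
    Partial = as.logical(tbl$Partial),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$Partial)))
    stop("unparsable Partial value in ", path)
  if (!all(out$Strand %in% c(1L, -1L)))
    stop("Strand must be 1 or -1 in ", path)
  bad <- which(out$Left > out$Right)
  if (length(bad) > 0L)
    stop("Left > Right in ", path, " at data line ", bad[1L])
  if (any(out$Left < 1L))
    stop("coordinates must be >= 1 in ", path)
  out
}

#' Merge gene predictions from several gene finders
#'
#' Compiles the union of several prediction sets for the same genome into one
#' list of ORFs. Predictions are keyed by their stop codon: on the + strand
#' the stop codon sits at the \code{Right} coordinate, on the - strand at
#' \code{Left}. When the same stop codon has alternative starts (the typical
#' disagreement between gene finders), only the longest ORF is kept; the
#' subsequent Pfam filtering is relied upon to weed out over-extended calls.
#' All partial ORFs are eliminated before merging.
#'
#' @param prediction_sets a list of prediction \code{data.frame}s as returned
#'   by \code{\link{read_predictions}} (a single \code{data.frame} is also
#'   accepted).
#'
#' @return A single prediction \code{data.frame} sorted by
#'   \code{(GenomeSequence, Left)}, with duplicates and partial ORFs removed.
#'
#' @export
merge_predictions <- function(prediction_sets) {
  if (is.data.frame(prediction_sets)) prediction_sets <- list(prediction_sets)
  all <- do.call(rbind, prediction_sets)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(GenomeSequence = character(), Strand = integer(),
                      Left = integer(), Right = integer(),
                      Partial = logical(), stringsAsFactors = FALSE))
  }
  all <- all[!all$Partial, , drop = FALSE]
  if (nrow(all) > 0L) {
    stop_anchor <- ifelse(all$Strand == 1L, all$Right, all$Left)
    key <- paste(all$GenomeSequence, all$Strand, stop_anchor, sep = "\r")
    len <- all$Right - all$Left + 1L
    # longest ORF per stop-codon key
    ord <- order(key, -len)
    all <- all[ord, , drop = FALSE]
    all <- all[!duplicated(key[ord]), , drop = FALSE]
  }
  all <- all[order(all$GenomeSequence, all$Left, all$Right, all$Strand), ,
             drop = FALSE]
  rownames(all) <- NULL
  all
}

# table-11 alternative initiator codons (all rendered as M at ORF start)
.start_codons_11 <- c("TTG", "CTG", "ATT", "ATC", "ATA", "ATG", "GTG")

#' Translate merged ORFs to protein
#'
#' Extracts each predicted ORF from the genome sequence, reverse-complements
#' minus-strand predictions, and translates with the bacterial genetic code
#' (translation table 11). Alternative initiator codons (GTG, TTG, ...) are
#' rendered as M; the trailing stop codon is removed. Predictions whose
#' translation contains an internal stop codon are skipped with a warning --
#' the union of several gene finders is expected to contain such errors, and
#' they are filtered out later by the Pfam scan anyway.
#'
#' @param genome a named \code{\link[Biostrings]{DNAStringSet}} of genome
#'   sequences, or the path to a FASTA file of them. Names must match the
#'   \code{GenomeSequence} column of \code{predictions} (FASTA descriptions
#'   are truncated at the first whitespace).
#' @param predictions a prediction \code{data.frame}, normally the output of
#'   \code{\link{merge_predictions}}; partial predictions are not allowed.
#' @param genome_id label used to build protein identifiers; defaults to
#'   \code{"genome"}.
#'
#' @return A named \code{\link[Biostrings]{AAStringSet}}; names are protein
#'   identifiers \code{<genome_id>_orf<n>} numbered in prediction order.
#'   The number of skipped predictions is attached as attribute
#'   \code{"n_skipped"}.
#'
#' @export
translate_orfs <- function(genome, predictions, genome_id = "genome") {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(predictions$Partial))
    stop("translate_orfs: partial predictions must be eliminated first")
  n <- nrow(predictions)
  ids <- sprintf("%s_orf%04d", genome_id, seq_len(n))
  aas <- character(n)
  keep <- logical(n)
  n_internal <- 0L
  code11 <- Biostrings::getGeneticCode("11")
  for (i in seq_len(n)) {
    sid <- predictions$GenomeSequence[i]
    if (!sid %in% names(genome))
      stop("prediction ", ids[i], ": genome sequence '", sid, "' not found")
    gseq <- genome[[sid]]
    l <- predictions$Left[i]; r <- predictions$Right[i]
    if (r > length(gseq))
      stop("prediction ", ids[i], " (", sid, ":", l, "-", r,
           "): coordinate outside sequence of length ", length(gseq))
    if ((r - l + 1L) %% 3L != 0L)
      stop("prediction ", ids[i], ": length not divisible by 3")
    orf <- Biostrings::subseq(gseq, l, r)
    if (predictions$Strand[i] == -1L)
      orf <- Biostrings::reverseComplement(orf)
    aa <- as.character(Biostrings::translate(orf, genetic.code = code11))
    first_codon <- as.character(Biostrings::subseq(orf, 1L, 3L))
    if (first_codon %in% .start_codons_11)
      substr(aa, 1L, 1L) <- "M"
    if (substr(aa, nchar(aa), nchar(aa)) == "*")
      aa <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("*", aa, fixed = TRUE)) {
      n_internal <- n_internal + 1L
      next
    }
    if (nchar(aa) == 0L) {
      n_internal <- n_internal + 1L
      next
    }
    aas[i] <- aa
    keep[i] <- TRUE
  }
  if (n_internal > 0L)
    warning("translate_orfs: skipped ", n_internal,
            " prediction(s) with internal stop codons")
  out <- Biostrings::AAStringSet(aas[keep])
  names(out) <- ids[keep]
  attr(out, "n_skipped") <- n_internal
  out
}

#' Jaccard distance between two protein sets
#'
#' The Jaccard distance J(Sa, Sb) = 1 - |Sa intersect Sb| / |Sa union Sb|
#' between two collections of proteins. In \code{"exact-sequence"} mode two
#' proteins are equal only when their amino-acid sequences are identical; in
#' \code{"domain-sequence"} mode elements are domain-sequence keys (ordered
#' Pfam accession lists), and empty keys -- proteins without any Pfam hit --
#' are discarded before comparison. Collections are de-duplicated, so the
#' distance depends only on the underlying sets. The distance of two empty
#' sets is defined as 0 (they are identical).
#'
#' @param set_a,set_b character vectors (amino-acid sequences or
#'   domain-sequence keys), or \code{AAStringSet}s.
#' @param mode \code{"exact-sequence"} or \code{"domain-sequence"}.
#'
#' @return A single number in \code{[0, 1]}.
#'
#' @examples
#' jaccard_protein_sets(c("MAA", "MBB"), c("MAA", "MCC"))  # 1 - 1/3
#'
#' @export
jaccard_protein_sets <- function(set_a, set_b,
                                 mode = c("exact-sequence", "domain-sequence")) {
  mode <- match.arg(mode)
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  if (mode == "domain-sequence") {
    a <- a[!is.na(a) & nzchar(a)]
    b <- b[!is.na(b) & nzchar(b)]
  }
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

#' Solve the Jaccard distance for per-list unique counts
#'
#' For two protein lists of equal size n with a symmetric non-overlap (the
#' same number u of proteins on each list absent from the other), the Jaccard
#' distance is J = 2u / (n + u). This inverts that relation: given n and J it
#' returns u, the number of proteins on each list not found in the other.
#'
#' @param n size of each list.
#' @param jaccard Jaccard distance in \code{[0, 1)}.
#'
#' @return The per-list unique count u (not rounded).
#'
#' @examples
#' jaccard_unique_count(5000, 0.26)  # about 750 per list
#'
#' @export
jaccard_unique_count <- function(n, jaccard) {
  stopifnot(n > 0, jaccard >= 0, jaccard < 1)
  jaccard * n / (2 - jaccard)
}

#' Convert an expected genome overlap to a mean Jaccard distance
#'
#' For two equal-sized genomes each sharing a fraction \code{overlap} of its
#' families with the other, the Jaccard distance is
#' 1 - overlap / (2 - overlap). An expected two-genome overlap of 0.90 thus
#' corresponds to a mean Jaccard distance of about 0.18.
#'
#' @param overlap expected fraction of one genome's families also present in
#'   the other, in \code{(0, 1]}.
#'
#' @return The corresponding Jaccard distance.
#'
#' @export
overlap_to_jaccard <- function(overlap) {
  stopifnot(overlap > 0, overlap <= 1)
  1 - overlap / (2 - overlap)
}
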