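#' Parse an HMMER3 domtblout file
#'
#' Reads the per-domain table written by \code{hmmscan --domtblout} (HMMER3).
#' Comment lines starting with \code{#} are ignored. Data lines are
#' whitespace-delimited with at least 23 fields; the trailing free-text
#' description is ignored. The fields retained per domain hit are the target
#' (Pfam) accession, the query protein name, the independent E-value
#' (iEvalue), the domain bit score, and the alignment and envelope
#' coordinates on the protein (1-based inclusive).
#'
#' @param path path to a domtblout file.
#'
#' @return A \code{data.frame} with columns \code{query} (protein id),
#'   \code{accession} (versioned Pfam accession as read, e.g.
#'   \code{PF07690.11}), \code{ievalue}, \code{score}, \code{ali_from},
#'   \code{ali_to}, \code{env_from}, \code{env_to}; one row per domain hit.
#'
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) stop("domtblout file not found: ", path)
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  empty <- data.frame(query = character(), accession = character(),
                      ievalue = numeric(), score = numeric(),
                      ali_from = integer(), ali_to = integer(),
                      env_from = integer(), env_to = integer(),
                      stringsAsFactors = FALSE)
  if (length(data_idx) == 0L) return(empty)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 23L))
    stop("domtblout ", path, ": line ", data_idx[which(nf < 23L)[1L]],
         " has fewer than 23 fields")
  grab <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(x, what, as_int = FALSE) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop("domtblout ", path, ": unparsable ", what, " '", x[bad[1L]],
           "' at line ", data_idx[bad[1L]])
    if (as_int) as.integer(v) else v
  }
  out <- data.frame(
    query = grab(4L),
    accession = grab(2L),
    ievalue = num(grab(13L), "i-Evalue"),
    score = num(grab(14L), "score"),
    ali_from = num(grab(18L), "ali from", TRUE),
    ali_to = num(grab(19L), "ali to", TRUE),
    env_from = num(grab(20L), "env from", TRUE),
    env_to = num(grab(21L), "env to", TRUE),
    stringsAsFactors = FALSE
  )
  if (any(out$ievalue < 0))
    stop("domtblout ", path, ": negative i-Evalue")
  if (any(out$ali_from > out$ali_to))
    stop("domtblout ", path, ": ali_from > ali_to")
  out
}

#' Filter domain hits by independent E-value
#'
#' Keeps hits with iEvalue at or below a cutoff. With \code{cutoff = NULL}
#' all hits pass: the curated Pfam gathering (GA) thresholds were already
#' applied inside \code{hmmscan --cut_ga}, and the E-value cutoff is only
#' used to impose a stricter level of significance on top of them.
#'
#' @param hits a hit \code{data.frame} from \code{\link{parse_domtblout}}.
#' @param cutoff positive E-value cutoff, or \code{NULL} for no extra
#'   filtering.
#'
#' @return The filtered hit \code{data.frame}, input order preserved.
#'
#' @export
filter_hits <- function(hits, cutoff = NULL) {
  if (is.null(cutoff)) return(hits)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0)
    stop("cutoff must be a single non-negative number or NULL")
  out <- hits[hits$ievalue <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain hits on one protein
#'
#' When two or more retained domains overlap on the protein (share at least
#' one position of their alignment intervals; nesting counts as overlap), the
#' hit with the largest iEvalue among all hits currently involved in any
#' overlap is eliminated, and this is repeated recursively until no overlaps
#' remain. Ties on iEvalue are broken deterministically: the shorter
#' alignment is removed first, then the one with the larger \code{ali_from},
#' then the lexicographically larger accession.
#'
#' @param hits a hit \code{data.frame} for a single query protein.
#'
#' @return The retained hits, pairwise non-overlapping, sorted by
#'   \code{ali_from}.
#'
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) > 0L && length(unique(hits$query)) > 1L)
    stop("resolve_overlaps expects hits for a single query protein")
  keep <- hits
  repeat {
    n <- nrow(keep)
    if (n <= 1L) break
    from <- keep$ali_from; to <- keep$ali_to
    # ov[i] TRUE when hit i overlaps any other retained hit
    ov <- vapply(seq_len(n), function(i) {
      any(from[-i] <= to[i] & to[-i] >= from[i])
    }, logical(1L))
    if (!any(ov)) break
    cand <- which(ov)
    len <- to[cand] - from[cand] + 1L
    # eliminate: largest iEvalue; ties -> shorter alignment, larger
    # ali_from, lexicographically larger accession
    o <- order(keep$ievalue[cand], len, from[cand], keep$accession[cand],
               decreasing = c(TRUE, FALSE, TRUE, TRUE), method = "radix")
    keep <- keep[-cand[o[1L]], , drop = FALSE]
  }
  keep <- keep[order(keep$ali_from, keep$ali_to), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Strip Pfam version suffixes
#'
#' Removes the \code{.nn} version suffix from Pfam accessions
#' (\code{PF07690.11} becomes \code{PF07690}). Idempotent.
#'
#' @param accessions character vector of accessions.
#' @return Character vector without version suffixes.
#' @export
strip_versions <- function(accessions) {
  sub("\\.\\d+$", "", accessions)
}

#' The domain sequence of one protein
#'
#' The domain sequence is the ordered list of Pfam accessions of the
#' non-overlapping hits along the protein, a high-level alternative to the
#' amino-acid representation. Multiple hits of the same domain may occur as
#' long as they do not overlap. The canonical key joins the accessions with
#' commas; by default version suffixes are stripped so that keys are robust
#' across Pfam releases.
#'
#' @param resolved_hits pairwise non-overlapping hits for one protein, as
#'   returned by \code{\link{resolve_overlaps}}.
#' @param keep_versions keep the \code{.nn} version suffix in the key.
#'
#' @return The domain-sequence key (a single string), or \code{NA_character_}
#'   for an empty hit set (the protein carries no domain and is discarded
#'   from the downstream analysis).
#'
#' @export
domain_sequence <- function(resolved_hits, keep_versions = FALSE) {
  n <- nrow(resolved_hits)
  if (n == 0L) return(NA_character_)
  from <- resolved_hits$ali_from; to <- resolved_hits$ali_to
  if (n > 1L) {
    o <- order(from, to)
    from <- from[o]; to <- to[o]
    if (any(from[-1L] <= to[-n]))
      stop("domain_sequence: hits overlap; run resolve_overlaps first")
    acc <- resolved_hits$accession[o]
  } else {
    acc <- resolved_hits$accession
  }
  if (!keep_versions) acc <- strip_versions(acc)
  paste(acc, collapse = ",")
}

#' Domain sequences for all proteins in one genome scan
#'
#' Convenience wrapper: groups a genome's domtblout hits by query protein,
#' applies the E-value filter and the recursive overlap elimination, and
#' returns the domain-sequence key of every protein with at least one
#' retained hit. Proteins without hits are dropped.
#'
#' @param hits hit \code{data.frame} for one genome
#'   (\code{\link{parse_domtblout}}).
#' @param cutoff optional iEvalue cutoff passed to \code{\link{filter_hits}}.
#' @param keep_versions keep Pfam version suffixes in keys.
#'
#' @return Named character vector of domain-sequence keys; names are protein
#'   ids in their order of first appearance in the file.
#'
#' @export
genome_domain_sequences <- function(hits, cutoff = NULL,
                                    keep_versions = FALSE) {
  hits <- filter_hits(hits, cutoff)
  if (nrow(hits) == 0L) return(stats::setNames(character(), character()))
  qorder <- unique(hits$query)
  keys <- vapply(qorder, function(q) {
    h <- resolve_overlaps(hits[hits$query == q, , drop = FALSE])
    domain_sequence(h, keep_versions = keep_versions)
  }, character(1L))
  keys[!is.na(keys)]
}

#' Group proteins into domain sequence families
#'
#' All proteins having an identical domain sequence form one domain sequence
#' family. Families are labelled \code{"Cluster 1"}, \code{"Cluster 2"}, ...
#' in order of first appearance, iterating genomes in input order and
#' proteins in file order, so the labels are reproducible.
#'
#' @param per_genome named list; one element per genome holding the named
#'   vector of domain-sequence keys from
#'   \code{\link{genome_domain_sequences}}.
#'
#' @return An object of class \code{"family_catalog"}: a list with
#'   \describe{
#'     \item{families}{\code{data.frame(family_id, key)} in first-seen order}
#'     \item{members}{\code{data.frame(genome, protein_id, family_id)}}
#'   }
#'
#' @export
build_families <- function(per_genome) {
  if (length(per_genome) > 0L && is.null(names(per_genome)))
    names(per_genome) <- paste0("genome", seq_along(per_genome))
  keys_all <- unlist(per_genome, use.names = FALSE)
  if (is.null(keys_all)) keys_all <- character()
  uniq <- unique(keys_all)
  fam_ids <- if (length(uniq) > 0L) paste("Cluster", seq_along(uniq)) else character()
  members <- data.frame(
    genome = rep(names(per_genome), times = vapply(per_genome, length, 0L)),
    protein_id = unlist(lapply(per_genome, names), use.names = FALSE),
    family_id = fam_ids[match(keys_all, uniq)],
    stringsAsFactors = FALSE
  )
  structure(list(
    families = data.frame(family_id = fam_ids, key = uniq,
                          stringsAsFactors = FALSE),
    members = members,
    genomes = names(per_genome)
  ), class = "family_catalog")
}

#' @export
print.family_catalog <- function(x, ...) {
  cat("Domain sequence family catalog:", nrow(x$families), "families,",
      nrow(x$members), "proteins,", length(x$genomes), "genomes\n")
  invisible(x)
}

#' Histogram of domain-sequence lengths
#'
#' Counts how many distinct domain sequence families have 1 domain, 2
#' domains, ... up to the longest family. Counts are over family keys, not
#' member proteins.
#'
#' @param catalog a \code{\link{build_families}} catalog.
#'
#' @return Named integer vector; element \code{"k"} is the number of
#'   families whose domain sequence has k domains. Empty catalog gives an
#'   empty vector.
#'
#' @export
length_histogram <- function(catalog) {
  keys <- catalog$families$key
  if (length(keys) == 0L) return(stats::setNames(integer(), character()))
  ndom <- lengths(strsplit(keys, ",", fixed = TRUE))
  counts <- tabulate(ndom, nbins = max(ndom))
  stats::setNames(as.integer(counts), as.character(seq_len(max(ndom))))
}

#' Write a cluster_info table
#'
#' Writes the two-column tab-separated table mapping family ids
#' (\code{Cluster n}) to their comma-joined ordered Pfam accession lists.
#'
#' @param catalog a \code{\link{build_families}} catalog.
#' @param path output path.
#' @export
write_cluster_info <- function(catalog, path) {
  utils::write.table(catalog$families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
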