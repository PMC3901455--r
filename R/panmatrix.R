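#' Build the pan-matrix
#'
#' The pan-matrix is the fundamental data structure of a pangenome analysis:
#' one row per genome, one column per domain sequence family, and cell
#' (i, j) holding the number of copies of family j in genome i. Presence /
#' absence is derived as \code{counts > 0}. All-zero columns cannot occur by
#' construction -- a family exists only because some genome contains it.
#'
#' @param catalog a \code{\link{build_families}} catalog.
#'
#' @return An integer matrix of class \code{"panmat"} with genome row names
#'   and family-id column names.
#'
#' @export
build_panmatrix <- function(catalog) {
  genomes <- catalog$genomes
  fams <- catalog$families$family_id
  if (length(genomes) == 0L || length(fams) == 0L)
    stop("build_panmatrix: catalog is empty")
  m <- matrix(0L, nrow = length(genomes), ncol = length(fams),
              dimnames = list(genomes, fams))
  tab <- table(factor(catalog$members$genome, levels = genomes),
               factor(catalog$members$family_id, levels = fams))
  m[] <- as.integer(tab)
  structure(m, class = c("panmat", "matrix"))
}

#' Construct a panmat from a plain matrix
#'
#' @param counts non-negative integer matrix, genomes in rows, families in
#'   columns; row and column names are kept (defaults are generated).
#' @return A \code{"panmat"} object.
#' @export
as_panmat <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("pan-matrix counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("genome", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste("Cluster", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  keep <- colSums(counts > 0) > 0
  counts <- counts[, keep, drop = FALSE]
  structure(counts, class = c("panmat", "matrix"))
}

#' @export
print.panmat <- function(x, ...) {
  sp <- spectrum_summary(x)
  cat("Pan-matrix:", nrow(x), "genomes x", ncol(x), "domain sequence families\n")
  cat("  core families (in all genomes):", sp$core, "\n")
  cat("  ORFan families (in one genome):", sp$orfans, "\n")
  invisible(x)
}

#' @exportS3Method base::summary
summary.panmat <- function(object, ...) {
  sp <- spectrum_summary(object)
  cat("Pan-matrix of", nrow(object), "genomes and", sp$pangenome,
      "domain sequence families\n")
  cat("Family frequency spectrum y_g (g = 1..G):\n")
  print(sp$y)
  invisible(sp)
}

#' Family frequency spectrum of a pan-matrix
#'
#' Let x_j be the number of genomes in which family j is present and y_g the
#' number of families with x_j = g. The spectrum y_1..y_G summarises the
#' pan-matrix: y_1 is the number of ORFan families (present in one genome
#' only), y_G the number of core families (present in every genome), and the
#' sum of all y_g the sample pangenome size M.
#'
#' @param pm a \code{"panmat"} (or plain counts matrix).
#'
#' @return A list with \code{y} (named integer vector, g = 1..G),
#'   \code{core} (= y_G), \code{orfans} (= y_1) and \code{pangenome} (= M).
#'
#' @export
spectrum_summary <- function(pm) {
  G <- nrow(pm)
  x <- colSums(pm > 0)
  y <- tabulate(x, nbins = G)
  names(y) <- seq_len(G)
  list(y = y, core = y[[G]], orfans = y[[1L]], pangenome = sum(y))
}

#' Pairwise Manhattan distances between genomes
#'
#' The distance between two genomes is the number of domain sequence
#' families in which they differ in presence/absence status (copy numbers
#' are ignored): a distance of 500 means 500 families are contained in one
#' genome but not the other. Rows of the presence/absence pan-matrix are
#' coordinates in a functional space, and this is the natural metric there.
#'
#' @param pm a \code{"panmat"}.
#' @return A symmetric G x G matrix of counts with zero diagonal.
#' @export
manhattan_distances <- function(pm) {
  if (nrow(pm) < 2L) stop("need at least 2 genomes")
  p <- (unclass(pm) > 0) * 1
  as.matrix(stats::dist(p, method = "manhattan"))
}

#' Pairwise Jaccard distances and genome fluidity
#'
#' Computes, on family presence sets, the Jaccard distance between every
#' genome pair, its mean over unordered pairs, and the genome fluidity: for
#' a pair (a, b) the ratio of families unique to either genome over their
#' total family counts, (U_a + U_b) / (|S_a| + |S_b|), averaged over pairs.
#' Both measures quantify lack of overlap; both depend only on presence, not
#' copy number.
#'
#' @param pm a \code{"panmat"}.
#'
#' @return A list with \code{jaccard} (G x G matrix), \code{mean_jaccard}
#'   and \code{fluidity}.
#'
#' @export
genome_jaccard_and_fluidity <- function(pm) {
  if (nrow(pm) < 2L) stop("need at least 2 genomes")
  p <- (unclass(pm) > 0) * 1
  inter <- tcrossprod(p)
  sizes <- diag(inter)
  tot <- outer(sizes, sizes, "+")
  uni <- tot - inter                    # |union| for each pair
  jac <- 1 - inter / uni
  jac[uni == 0] <- 0                    # two empty genomes are identical
  diag(jac) <- 0
  flu <- (tot - 2 * inter) / tot
  flu[tot == 0] <- 0
  diag(flu) <- 0
  ut <- upper.tri(jac)
  list(jaccard = jac, mean_jaccard = mean(jac[ut]), fluidity = mean(flu[ut]))
}

#' Core / ORFan counts along a sweep of E-value cutoffs
#'
#' Re-runs the whole family construction -- E-value filtering, recursive
#' overlap elimination, family grouping, pan-matrix -- at each cutoff and
#' reports the number of core and ORFan families. The sweep shows how the
#' uncertain ORFan families melt away under stricter significance while the
#' core is hardly touched. Each cutoff restarts from the raw hits: removing
#' a hit can change a protein's family identity, not just delete it, so no
#' incremental shortcut is taken.
#'
#' @param hits_per_genome named list of raw hit \code{data.frame}s
#'   (\code{\link{parse_domtblout}}), one per genome.
#' @param cutoffs numeric vector of iEvalue cutoffs; \code{NA} entries mean
#'   no extra cutoff (GA thresholds only).
#' @param keep_versions keep Pfam version suffixes in family keys.
#'
#' @return \code{data.frame(cutoff, core, orfans, pangenome)}, one row per
#'   cutoff.
#'
#' @export
cutoff_sweep <- function(hits_per_genome, cutoffs, keep_versions = FALSE) {
  res <- lapply(cutoffs, function(ct) {
    ct_use <- if (is.na(ct)) NULL else ct
    per_genome <- lapply(hits_per_genome, genome_domain_sequences,
                         cutoff = ct_use, keep_versions = keep_versions)
    if (all(vapply(per_genome, length, 0L) == 0L))
      return(data.frame(cutoff = ct, core = 0L, orfans = 0L,
                        pangenome = 0L))
    cat_ <- build_families(per_genome[vapply(per_genome, length, 0L) > 0L])
    sp <- spectrum_summary(build_panmatrix(cat_))
    data.frame(cutoff = ct, core = sp$core, orfans = sp$orfans,
               pangenome = sp$pangenome)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Principal component scores of the presence/absence pan-matrix
#'
#' Projects the genomes onto the dominant directions of the functional
#' space. The presence/absence matrix is column-centred but not scaled
#' (columns are already on a common 0/1 scale), and components are ordered
#' by non-increasing explained variance.
#'
#' @param pm a \code{"panmat"}.
#' @param n_components number of components to return; at most
#'   \code{min(G - 1, M)}.
#'
#' @return A list with \code{scores} (G x n_components matrix) and
#'   \code{variance_fraction} (fraction of total variance per component).
#'
#' @export
pca_scores <- function(pm, n_components = 2L) {
  G <- nrow(pm)
  if (G < 2L) stop("need at least 2 genomes")
  if (n_components > min(G - 1L, ncol(pm)))
    stop("n_components exceeds min(G - 1, number of families)")
  p <- (unclass(pm) > 0) * 1
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  if (tot == 0) scores[] <- 0
  list(scores = scores, variance_fraction = vf[k])
}

#' Pangenome tree from genome distances
#'
#' Builds a pangenome tree by average-linkage (UPGMA) hierarchical
#' clustering of a genome distance matrix, typically the Manhattan distances
#' in presence/absence space, and returns it as a Newick string.
#'
#' @param distances symmetric G x G distance matrix with zero diagonal.
#' @param genome_names leaf labels; defaults to the matrix row names.
#' @param linkage clustering linkage, default \code{"average"}.
#'
#' @return A Newick tree string terminated by \code{";"}.
#'
#' @export
pangenome_tree <- function(distances, genome_names = rownames(distances),
                           linkage = "average") {
  distances <- as.matrix(distances)
  if (!isSymmetric(unname(distances), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  if (is.null(genome_names))
    genome_names <- paste0("genome", seq_len(nrow(distances)))
  rownames(distances) <- colnames(distances) <- genome_names
  hc <- stats::hclust(stats::as.dist(distances), method = linkage)
  ape::write.tree(ape::as.phylo(hc))
}

#' Write / read a pan-matrix as tab-separated text
#'
#' \code{write_panmatrix} writes the genomes x families copy-number table
#' with genome row names and \code{Cluster n} column names;
#' \code{read_panmatrix} reads it back. The round trip preserves counts
#' exactly.
#'
#' @param pm a \code{"panmat"}.
#' @param path file path.
#' @return \code{read_panmatrix} returns a \code{"panmat"}.
#' @export
write_panmatrix <- function(pm, path) {
  df <- as.data.frame(unclass(pm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_panmatrix
#' @export
read_panmatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, quote = "", comment.char = "")
  as_panmat(as.matrix(df))
}
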