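## Synthetic data with the statistical structure the analysis assumes:
## a pan-matrix sampled from a planted binomial mixture, and full on-disk
## fixture sets (genome FASTA, gene-prediction tables, domtblout scans)
## with a truth manifest, so every pipeline stage is testable without any
## external download.

#' Simulate a pan-matrix from a planted binomial mixture
#'
#' Each of N pangenome families draws a mixture component with
#' probabilities \code{pi} and is then present in each of G genomes
#' independently with that component's selection probability \code{rho}.
#' Families observed in no genome are dropped from the returned pan-matrix
#' (exactly the zero-truncation the downstream estimator corrects for) but
#' kept in the recorded truth. Copy numbers are presence (0/1).
#'
#' @param N planted population pangenome size.
#' @param G number of genomes.
#' @param pi mixing proportions (sum to 1).
#' @param rho selection probabilities in \code{(0, 1]}, same length as
#'   \code{pi}.
#' @param seed optional integer seed; the simulation is reproducible given
#'   the seed.
#'
#' @return A list with \code{pm} (a \code{"panmat"} of the observed
#'   families) and \code{truth}: \code{N_true}, \code{pi}, \code{rho},
#'   \code{G}, \code{seed}, per-family \code{component} assignments and the
#'   logical \code{observed} mask.
#'
#' @examples
#' sim <- simulate_panmatrix(200, 10, pi = c(0.4, 0.6),
#'                           rho = c(1, 0.2), seed = 1)
#' summary(sim$pm)
#'
#' @export
simulate_panmatrix <- function(N, G, pi, rho, seed = NULL) {
  if (length(pi) != length(rho)) stop("pi and rho must have equal length")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (any(pi < 0)) stop("pi must be non-negative")
  if (any(rho <= 0 | rho > 1)) stop("rho must be in (0, 1]")
  stopifnot(N >= 1, G >= 1)
  with_seed(seed, {
    comp <- sample.int(length(pi), N, replace = TRUE, prob = pi)
    pres <- matrix(stats::runif(G * N) < rep(rho[comp], each = G),
                   nrow = G, ncol = N)
    observed <- colSums(pres) > 0
    m <- pres[, observed, drop = FALSE] * 1L
    rownames(m) <- sprintf("genome%03d", seq_len(G))
    colnames(m) <- sprintf("Fam%05d", which(observed))
    list(pm = as_panmat(m),
         truth = list(N_true = N, pi = pi, rho = rho, G = G, seed = seed,
                      component = comp, observed = observed))
  })
}

# fixed reverse-translation table: one codon per amino acid (table 11)
.codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

.random_protein <- function(len) {
  paste0("M", paste(sample(names(.codon_of), len - 1L, replace = TRUE),
                    collapse = ""))
}

.back_translate <- function(aa) {
  paste0(paste(.codon_of[strsplit(aa, "")[[1L]]], collapse = ""), "TAA")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# one domtblout data line with the 23-field contract
.domtbl_line <- function(acc, query, qlen, ievalue, from, to) {
  paste(sub("\\..*$", "", acc), acc, to - from + 20L, query, "-", qlen,
        format(ievalue / 10, digits = 3), "55.1", "0.1", "1", "1",
        format(ievalue / 100, digits = 3), format(ievalue, digits = 3),
        "54.8", "0.1", "2", to - from + 1L, from, to,
        max(1L, from - 2L), to + 2L, "0.95", "Synthetic domain model")
}

#' Write a synthetic fixture set for the whole pipeline
#'
#' Fabricates, per genome, a genome FASTA, two gene-prediction tables (as
#' if from two gene finders) and an \code{hmmscan --domtblout} result file,
#' together with a truth manifest of every protein's intended final domain
#' sequence. The planted cases exercise the pipeline's decision points: an
#' alternative shorter start sharing a stop codon (the longer ORF must
#' win), a partial prediction (must be eliminated), minus-strand ORFs, a
#' protein without any domain hit (discarded downstream), and a decoy
#' domain hit overlapping a better one (eliminated by the recursive overlap
#' resolution). Family presence across genomes follows a planted binomial
#' mixture, so the resulting spectrum has the shape the estimators assume.
#'
#' @param n_genomes number of genomes to fabricate.
#' @param n_families number of distinct domain-architecture families in the
#'   planted pangenome.
#' @param seed integer seed; fixture sets are reproducible given the seed.
#' @param out_dir output directory (created if needed).
#' @param pi,rho planted mixture over family selection probabilities.
#'
#' @return Invisibly, a list with \code{manifest}
#'   (\code{data.frame(genome, protein_id, key)}; empty key = no domains),
#'   \code{files} (per-genome named list with \code{genome}, \code{pred1},
#'   \code{pred2}, \code{domtbl}), \code{genome_ids} and the planted
#'   \code{architectures}. The manifest is also written to
#'   \code{manifest.txt} in \code{out_dir}.
#'
#' @export
simulate_domain_fixtures <- function(n_genomes, n_families, seed = NULL,
                                     out_dir = tempfile("fixtures"),
                                     pi = c(0.3, 0.3, 0.4),
                                     rho = c(1.0, 0.6, 0.2)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    if (n_families > 0L) {
      arch_len <- sample(1:4, n_families, replace = TRUE,
                         prob = c(0.55, 0.25, 0.12, 0.08))
      acc_pool <- sprintf("PF%05d.%d", seq_len(max(10L, n_families)),
                          sample(5:25, max(10L, n_families), replace = TRUE))
      archs <- lapply(arch_len, function(l)
        sample(acc_pool, l, replace = TRUE))
      comp <- sample.int(length(pi), n_families, replace = TRUE, prob = pi)
      fam_rho <- rho[comp]
    } else {
      archs <- list(); fam_rho <- numeric()
    }
    genome_ids <- sprintf("g%02d", seq_len(n_genomes))
    manifest <- list()
    files <- list()
    for (gi in seq_len(n_genomes)) {
      gid <- genome_ids[gi]
      chr <- paste0(gid, "_chr")
      present <- which(stats::runif(n_families) < fam_rho)
      if (n_families > 0L && length(present) == 0L)
        present <- sample.int(n_families, 1L)
      # one domain-free protein per genome, discarded by the Pfam filter
      n_prot <- length(present) + 1L
      keys <- character(n_prot)
      prot_arch <- vector("list", n_prot)
      for (i in seq_along(present))
        prot_arch[[i]] <- archs[[present[i]]]
      strands <- ifelse(stats::runif(n_prot) < 0.3, -1L, 1L)
      # protein long enough for its domains: 40 residues per domain + margins
      plens <- 20L + 50L * pmax(1L, lengths(prot_arch))
      prots <- vapply(plens, .random_protein, character(1L))
      orfs <- vapply(prots, .back_translate, character(1L))
      # assemble the chromosome: ORFs separated by 10 bp spacers
      spacer <- "CCCCCCCCCC"
      pos <- 1L
      seq_parts <- character(0)
      pred <- data.frame(GenomeSequence = character(), Strand = integer(),
                         Left = integer(), Right = integer(),
                         Partial = logical(), stringsAsFactors = FALSE)
      for (i in seq_len(n_prot)) {
        seq_parts <- c(seq_parts, spacer)
        pos <- pos + nchar(spacer)
        orf_nt <- if (strands[i] == 1L) orfs[i] else .revcomp(orfs[i])
        left <- pos; right <- pos + nchar(orf_nt) - 1L
        seq_parts <- c(seq_parts, orf_nt)
        pos <- right + 1L
        pred <- rbind(pred, data.frame(GenomeSequence = chr,
                                       Strand = strands[i], Left = left,
                                       Right = right, Partial = FALSE,
                                       stringsAsFactors = FALSE))
      }
      seq_parts <- c(seq_parts, spacer)
      genome_seq <- paste(seq_parts, collapse = "")
      # finder 2 sees a subset, plus a shorter alternative start for the
      # first ORF (same stop codon) and a bogus partial call
      alt <- pred[1L, , drop = FALSE]
      if (alt$Strand == 1L) alt$Left <- alt$Left + 6L else
        alt$Right <- alt$Right - 6L
      partial <- data.frame(GenomeSequence = chr, Strand = 1L,
                            Left = 1L, Right = 8L, Partial = TRUE,
                            stringsAsFactors = FALSE)
      pred2 <- rbind(pred[seq_len(max(1L, n_prot %/% 2L)), , drop = FALSE],
                     alt, partial)
      # merged order is by Left; ids follow that order
      ord <- order(pred$Left)
      ids <- sprintf("%s_orf%04d", gid, seq_len(n_prot))
      # domtblout hits: real architecture hits plus one overlapping decoy
      lines <- c("#                     --- full sequence ---  (synthetic domtblout)",
                 "# target name  accession  tlen  query name ...")
      for (i in seq_len(n_prot)) {
        row <- which(ord == i)           # position of protein i after sort
        pid <- ids[row]
        aa_len <- plens[i]
        arch <- prot_arch[[i]]
        if (i <= length(present)) {
          keys[i] <- paste(strip_versions(arch), collapse = ",")
          evs <- 10^stats::runif(length(arch), -60, -2)
          start <- 10L
          for (d in seq_along(arch)) {
            lines <- c(lines, .domtbl_line(arch[d], pid, aa_len, evs[d],
                                           start, start + 39L))
            if (d == 1L) {
              # decoy overlapping the first real hit; its iEvalue exceeds
              # every real one, so the recursive elimination removes it
              lines <- c(lines, .domtbl_line("PF99999.1", pid, aa_len,
                                             1e-2, start + 20L,
                                             start + 59L))
            }
            start <- start + 50L
          }
        }                                 # last protein: no hits at all
      }
      manifest[[gid]] <- data.frame(
        genome = gid,
        protein_id = ids[order(ord)][seq_len(n_prot)],
        key = keys, stringsAsFactors = FALSE)
      f <- list(genome = file.path(out_dir, paste0(gid, ".fsa")),
                pred1 = file.path(out_dir, paste0(gid, "_pred1.txt")),
                pred2 = file.path(out_dir, paste0(gid, "_pred2.txt")),
                domtbl = file.path(out_dir, paste0(gid, "_domtbl.txt")))
      gs <- Biostrings::DNAStringSet(genome_seq)
      names(gs) <- chr
      Biostrings::writeXStringSet(gs, f$genome, width = 70L)
      utils::write.table(pred, f$pred1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(pred2, f$pred2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(lines, f$domtbl)
      files[[gid]] <- f
    }
    manifest <- do.call(rbind, manifest)
    if (is.null(manifest))
      manifest <- data.frame(genome = character(), protein_id = character(),
                             key = character(), stringsAsFactors = FALSE)
    rownames(manifest) <- NULL
    utils::write.table(manifest, file.path(out_dir, "manifest.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(manifest = manifest, files = files,
                   genome_ids = genome_ids, architectures = archs))
  })
}

#' Run the full pipeline on a fixture directory
#'
#' Convenience driver used by tests and the command line: for each genome,
#' reads and merges the gene predictions, translates the merged ORFs,
#' parses and filters the domtblout scan, resolves overlapping hits and
#' extracts domain sequences; then groups families across genomes and
#' builds the pan-matrix.
#'
#' @param files per-genome list as returned in \code{$files} by
#'   \code{\link{simulate_domain_fixtures}}: each element has paths
#'   \code{genome}, \code{domtbl} and one or more \code{pred*} entries.
#' @param cutoff optional iEvalue cutoff.
#' @param keep_versions keep Pfam version suffixes in family keys.
#'
#' @return A list with \code{proteins} (per-genome \code{AAStringSet}),
#'   \code{keys} (per-genome named key vectors), \code{catalog} and
#'   \code{pm}.
#'
#' @export
run_pipeline <- function(files, cutoff = NULL, keep_versions = FALSE) {
  per_genome <- list()
  proteins <- list()
  for (gid in names(files)) {
    f <- files[[gid]]
    preds <- lapply(f[grepl("^pred", names(f))], read_predictions)
    merged <- merge_predictions(preds)
    prot <- translate_orfs(f$genome, merged, genome_id = gid)
    proteins[[gid]] <- prot
    hits <- parse_domtblout(f$domtbl)
    hits <- hits[hits$query %in% names(prot), , drop = FALSE]
    per_genome[[gid]] <- genome_domain_sequences(hits, cutoff = cutoff,
                                                 keep_versions = keep_versions)
  }
  catalog <- build_families(per_genome)
  list(proteins = proteins, keys = per_genome, catalog = catalog,
       pm = build_panmatrix(catalog))
}
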