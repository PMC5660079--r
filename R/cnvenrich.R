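## Gene-level CNV enrichment: binary sample x gene overlap matrix, the
## carrier-proportion ratio ("KB score"), and a rank-based permutation test.

#' Map CNV calls to genes as a binary carrier matrix
#'
#' A CNV maps to a gene if they share at least one base pair
#' (`max(starts) <= min(stops)` on the same chromosome; 1-based inclusive).
#' Multiple CNVs of one sample inside one gene still yield a cell value of
#' 1: the matrix answers "is this gene affected?", not "how much?".
#'
#' @param calls a [cnv_calls()] table.
#' @param genes a `region_set` of gene spans.
#' @param samples character vector of sample ids (matrix rows).
#' @param phenotype 0/1 case-control vector aligned with `samples`.
#' @param state `"deletion"`, `"duplication"`, or `"any"`; calls of other
#'   states are ignored.
#' @return A `gene_overlap_matrix`: list with `matrix` (samples x genes,
#'   0/1), `phenotype`, `state`.
#' @export
map_cnvs_to_genes <- function(calls, genes, samples, phenotype,
                              state = c("deletion", "duplication", "any")) {
  state <- match.arg(state)
  stopifnot(length(phenotype) == length(samples))
  if (state != "any") calls <- calls[calls$state == state, , drop = FALSE]
  M <- matrix(0L, nrow = length(samples), ncol = nrow(genes),
              dimnames = list(samples, genes$name))
  for (g in seq_len(nrow(genes))) {
    hit <- calls$chrom == genes$chrom[g] &
      pmax(calls$start, genes$start[g]) <= pmin(calls$stop, genes$stop[g])
    if (any(hit))
      M[unique(calls$sample[hit]), g] <- 1L
  }
  structure(list(matrix = M, phenotype = as.integer(phenotype),
                 state = state),
            class = "gene_overlap_matrix")
}

#' Genes with enough carriers in both arms
#'
#' @param overlap a `gene_overlap_matrix`.
#' @param min_cases,min_controls minimum carrier counts (default 10 and 10).
#' @return Character vector of eligible gene names.
#' @export
filter_eligible_genes <- function(overlap, min_cases = 10, min_controls = 10) {
  ph <- overlap$phenotype
  cc <- colSums(overlap$matrix[ph == 1L, , drop = FALSE])
  ct <- colSums(overlap$matrix[ph == 0L, , drop = FALSE])
  colnames(overlap$matrix)[cc >= min_cases & ct >= min_controls]
}

#' Carrier-proportion ratio (KB score)
#'
#' `(case carriers / total cases) / (control carriers / total controls)`.
#' With zero control carriers but at least one case carrier the score is
#' `+Inf` (ranked above every finite score); with zero case carriers it
#' is 0.
#'
#' @param case_carriers,n_cases,control_carriers,n_controls counts
#'   (vectorized).
#' @export
kb_score <- function(case_carriers, n_cases, control_carriers, n_controls) {
  stopifnot(all(n_cases >= 1), all(n_controls >= 1))
  r <- (case_carriers / n_cases) / (control_carriers / n_controls)
  r[control_carriers == 0] <- Inf
  r[case_carriers == 0] <- 0
  r
}

## rank of the observed score among itself + permuted scores, largest = 1;
## an observed score tied with permuted scores is placed after them
kb_rank <- function(observed, permuted) {
  sum(permuted >= observed) + 1L
}

#' Rank-based permutation test for per-gene CNV enrichment
#'
#' The phenotype column is permuted `n_perm` times; each permutation scores
#' every gene (one shared permuted phenotype vector per iteration, so
#' carrier totals are conserved and runtime is O(n_perm * genes)).  For
#' each gene the observed KB score is ranked among itself plus its
#' `n_perm` permuted scores, largest first; an observed score tied with
#' permuted scores ranks after them (conservative).  `p = rank /
#' (n_perm + 1)`, bounded below by `1 / (n_perm + 1)`.  No multiplicity
#' correction is applied to these p-values.
#'
#' @param overlap a `gene_overlap_matrix`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; results are bit-identical across runs with the
#'   same seed.
#' @param genes genes to test; defaults to [filter_eligible_genes()] with
#'   `min_cases`/`min_controls`.
#' @param min_cases,min_controls eligibility bounds used for the default
#'   gene set.
#' @return A `kb_result` data.frame: `gene`, `case_carriers`,
#'   `control_carriers`, `kb_score`, `rank`, `p`.
#' @export
permutation_enrichment <- function(overlap, n_perm = 10000, seed = 1,
                                   genes = NULL, min_cases = 10,
                                   min_controls = 10) {
  stopifnot(n_perm >= 1)
  ph <- overlap$phenotype
  if (all(ph == 1L) || all(ph == 0L))
    stop("phenotype must contain both cases and controls")
  if (is.null(genes))
    genes <- filter_eligible_genes(overlap, min_cases, min_controls)
  if (length(genes) == 0L)
    stop("no eligible genes to test")
  M <- overlap$matrix[, genes, drop = FALSE]
  n_cases <- sum(ph == 1L)
  n_controls <- sum(ph == 0L)
  carriers <- colSums(M)
  cc_obs <- drop(crossprod(M, ph))
  ct_obs <- carriers - cc_obs
  obs <- kb_score(cc_obs, n_cases, ct_obs, n_controls)
  ge_count <- integer(length(genes))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      php <- sample(ph)
      cc <- drop(crossprod(M, php))
      sc <- kb_score(cc, n_cases, carriers - cc, n_controls)
      ge_count <- ge_count + (sc >= obs)
    }
  })
  rank <- ge_count + 1L
  structure(data.frame(gene = genes, case_carriers = as.integer(cc_obs),
                       control_carriers = as.integer(ct_obs),
                       kb_score = obs, rank = rank,
                       p = rank / (n_perm + 1),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("kb_result", "data.frame"))
}
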