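#' Genotype matrix container
#'
#' A light S3 container for a sites-by-samples table of biallelic SNP genotype
#' calls with per-sample read depths. Genotype calls are coded as integers:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' NA = missing. Sites are sorted by (chromosome, position) and positions are
#' 1-based (VCF native); interval-producing functions downstream convert to
#' 0-based half-open coordinates explicitly.
#'
#' @param sites data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `ref`, `alt` (single bases).
#' @param geno integer matrix, `nrow(sites)` x `length(samples)`, values in
#'   {0, 1, 2, NA}.
#' @param depth integer matrix of the same dimensions (NA where DP absent).
#' @param samples character vector of sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sites`, `geno`, `depth`, `samples`.
#' @export
genotype_matrix <- function(sites, geno, depth = NULL, samples = colnames(geno)) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  if (is.null(depth)) {
    depth <- matrix(NA_integer_, nrow(geno), ncol(geno))
  }
  depth <- as.matrix(depth)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  if (nrow(sites) != nrow(geno) || !all(dim(geno) == dim(depth)))
    stop("sites, geno and depth dimensions do not match")
  if (length(samples) != ncol(geno))
    stop("sample names do not match genotype columns")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    depth <- depth[ord, , drop = FALSE]
  }
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate (chromosome, position) in sites")
  rownames(sites) <- rownames(geno) <- rownames(depth) <- NULL
  colnames(geno) <- colnames(depth) <- samples
  structure(list(sites = sites, geno = geno, depth = depth, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d chromosome(s)\n",
              nrow(x$sites), length(x$samples), length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype matrix by site index
#' @param gm genotype_matrix
#' @param i integer or logical site index
#' @return genotype_matrix restricted to the selected sites
#' @export
subset_sites <- function(gm, i) {
  genotype_matrix(gm$sites[i, , drop = FALSE],
                  gm$geno[i, , drop = FALSE],
                  gm$depth[i, , drop = FALSE],
                  gm$samples)
}

#' Sample roles for lineage analyses
#'
#' Maps samples onto the roles the lineage comparisons need: `focal` (the
#' clonal sub-lineage under study), `reference` (wild-type relatives),
#' `reference_sister` (the reference samples forming the focal lineage's
#' sister clade; must be a subset of `reference`) and `outgroup`.
#'
#' @param focal,reference,reference_sister,outgroup character vectors of
#'   sample names. `reference_sister` defaults to all of `reference`.
#' @return An object of class `sample_roles`.
#' @export
sample_roles <- function(focal, reference, reference_sister = reference,
                         outgroup = character()) {
  stopifnot(length(focal) >= 1, length(reference) >= 1)
  if (!all(reference_sister %in% reference))
    stop("reference_sister must be a subset of reference")
  if (length(intersect(focal, reference)))
    stop("a sample cannot be both focal and reference")
  structure(list(focal = focal, reference = reference,
                 reference_sister = reference_sister, outgroup = outgroup),
            class = "sample_roles")
}

check_roles <- function(gm, roles) {
  known <- unlist(roles[c("focal", "reference", "outgroup")])
  missing <- setdiff(known, gm$samples)
  if (length(missing))
    stop("samples in roles but not in matrix: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
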