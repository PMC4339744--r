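#' Analysis configuration
#'
#' Validated bundle of file paths and options for the file-based
#' analysis path.  Exactly one relationship source must resolve:
#' `"pedigree"` (kinship from the `.fam`), `"grm"` (computed from the
#' genotypes themselves), or `"file"` (a GCTA-style text GRM).  A
#' prevalence vector is required iff the prevalence offset (MMQLS) is
#' chosen.
#'
#' @param bed_prefix PLINK fileset prefix.
#' @param pheno_path phenotype table (FID, IID, values; see
#'   [read_pheno_table]).
#' @param covar_path optional covariate table; an intercept is always
#'   prepended.
#' @param relationship one of `"pedigree"`, `"grm"`, `"file"`.
#' @param grm_path text GRM path (when `relationship = "file"`).
#' @param method score-test variant.
#' @param prevalence per-phenotype prevalence (MMQLS).
#' @param maf_min,hwe_min optional marker filters: minimum minor-allele
#'   frequency, minimum founders-only exact Hardy-Weinberg p-value
#'   (both `NULL` = off; these mirror common GWAS preprocessing and are
#'   not part of the test itself).
#' @param missing_code missing string in phenotype/covariate tables.
#' @param out_path results TSV path (optional).
#' @param seed integer seed recorded in the config.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(bed_prefix, pheno_path, covar_path = NULL,
                            relationship = c("pedigree", "grm", "file"),
                            grm_path = NULL,
                            method = c("MFQLS", "MMQLS", "MMASTOR"),
                            prevalence = NULL, maf_min = NULL,
                            hwe_min = NULL, missing_code = "NA",
                            out_path = NULL, seed = 1L) {
  relationship <- match.arg(relationship)
  method <- match.arg(method)
  if (relationship == "file" && is.null(grm_path))
    stop("relationship = 'file' requires grm_path")
  if (relationship != "file" && !is.null(grm_path))
    stop("grm_path given but relationship is not 'file'")
  if (method == "MMQLS" && is.null(prevalence))
    stop("the prevalence offset (MMQLS) requires a prevalence vector")
  if (method != "MMQLS" && !is.null(prevalence))
    warning("prevalence is ignored unless method = 'MMQLS'")
  structure(list(bed_prefix = bed_prefix, pheno_path = pheno_path,
                 covar_path = covar_path, relationship = relationship,
                 grm_path = grm_path, method = method,
                 prevalence = prevalence, maf_min = maf_min,
                 hwe_min = hwe_min, missing_code = missing_code,
                 out_path = out_path, seed = as.integer(seed)),
            class = "analysis_config")
}

# Founders-only exact Hardy-Weinberg test (Wigginton et al. recursion).
.hwe_exact_p <- function(n_het, n_hom_min, n_hom_maj) {
  n_rare <- 2L * n_hom_min + n_het
  n <- n_het + n_hom_min + n_hom_maj
  if (n == 0L) return(1)
  probs <- numeric(n_rare + 1L)
  mid <- floor(n_rare * (2 * n - n_rare) / (2 * n))
  if (mid %% 2L != n_rare %% 2L) mid <- mid + 1L
  probs[mid + 1L] <- 1
  het <- mid
  while (het >= 2L) {
    probs[het - 1L] <- probs[het + 1L] * het * (het - 1) /
      ((n_rare - het + 2) * (2 * n - n_rare - het + 2))
    het <- het - 2L
  }
  het <- mid
  while (het <= n_rare - 2L) {
    probs[het + 3L] <- probs[het + 1L] *
      (n_rare - het) * (2 * n - n_rare - het) /
      ((het + 2) * (het + 1))
    het <- het + 2L
  }
  probs <- probs / sum(probs)
  sum(probs[probs <= probs[n_het + 1L] * (1 + 1e-12)])
}

#' Load and align an analysis dataset
#'
#' Reads the genotype fileset, phenotype and covariate tables and the
#' relationship matrix named by an [analysis_config], aligns everything
#' on `fid:iid` (individuals present in the `.fam` but absent from the
#' phenotype table get all-missing phenotype rows, which are zeroed in
#' the adjusted phenotypes downstream), and applies the optional MAF and
#' founders-only exact HWE filters with logged counts.
#'
#' @param cfg an [analysis_config].
#' @return List: `ped`, `X`, `Y`, `Z` (with intercept), `phi`, `bim`.
#' @export
load_dataset <- function(cfg) {
  pl <- read_plink(cfg$bed_prefix)
  ids <- rownames(pl$X)
  ph <- read_pheno_table(cfg$pheno_path, cfg$missing_code)
  extra <- setdiff(ph$ids, ids)
  if (length(extra))
    stop("phenotype table contains unknown individuals: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  Y <- matrix(NA_real_, length(ids), ncol(ph$values),
              dimnames = list(ids, colnames(ph$values)))
  Y[ph$ids, ] <- ph$values
  Z <- matrix(1, length(ids), 1L, dimnames = list(ids, "intercept"))
  if (!is.null(cfg$covar_path)) {
    cv <- read_pheno_table(cfg$covar_path, cfg$missing_code)
    bad <- setdiff(cv$ids, ids)
    if (length(bad))
      stop("covariate table contains unknown individuals: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    Zc <- matrix(NA_real_, length(ids), ncol(cv$values),
                 dimnames = list(ids, colnames(cv$values)))
    Zc[cv$ids, ] <- cv$values
    Z <- cbind(Z, Zc)
  }
  phi <- switch(cfg$relationship,
                pedigree = kinship_from_pedigree(pl$fam),
                grm = grm_from_genotypes(pl$X),
                file = read_grm(cfg$grm_path, ids = ids))
  X <- pl$X
  bim <- pl$bim
  keep <- rep(TRUE, ncol(X))
  if (!is.null(cfg$maf_min)) {
    f <- colMeans(X, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    keep <- keep & maf >= cfg$maf_min
    message(sum(maf < cfg$maf_min), " marker(s) removed by MAF filter")
  }
  if (!is.null(cfg$hwe_min)) {
    fnd <- which(pl$fam$founder)
    hwe <- vapply(seq_len(ncol(X)), function(m) {
      g <- X[fnd, m]
      g <- g[!is.na(g)]
      .hwe_exact_p(sum(g == 1L), sum(g == 2L), sum(g == 0L))
    }, numeric(1))
    keep <- keep & hwe >= cfg$hwe_min
    message(sum(hwe < cfg$hwe_min), " marker(s) removed by HWE filter")
  }
  list(ped = pl$fam, X = X[, keep, drop = FALSE], Y = Y, Z = Z,
       phi = phi, bim = bim[keep, , drop = FALSE])
}

#' Association scan over markers or variant sets
#'
#' Fits the per-phenotype null mixed models once (the BLUP offset does
#' not depend on the tested markers under the null), then tests each
#' marker (`sets = NULL`) or each variant set jointly.  Individuals with
#' missing genotypes for a tested set are handled through the
#' conditional-expectation score ([mfqls_test_missing]).  Rows are
#' ordered by genomic position of the leading marker.
#'
#' @param data a dataset list from [load_dataset] (or with the same
#'   elements, built in memory).
#' @param method score-test variant.
#' @param sets optional named list of marker-id vectors.
#' @param prevalence per-phenotype prevalence (MMQLS).
#' @return Data frame: SET_ID, CHR, SNP_LIST, M, Q, METHOD, STAT, DF, P.
#' @export
run_scan <- function(data, method = c("MFQLS", "MMQLS", "MMASTOR"),
                     sets = NULL, prevalence = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(data$Y)
  phi <- data$phi
  miss_mask <- is.na(Y)
  if (method == "MMQLS") {
    if (is.null(prevalence)) stop("MMQLS requires prevalence")
    Tm <- prevalence_offset(Y, prevalence)
    Tw <- NULL
  } else {
    fits <- fit_null_model(Y, data$Z, phi)
    Tm <- blup_offset(Y, data$Z, phi, fits)
    Tw <- NULL
    if (method == "MMASTOR") {
      Tw <- Tm
      for (q in seq_len(ncol(Tm))) {
        H <- fits[[q]]$sigma2_B * phi +
          diag(fits[[q]]$sigma2_E, nrow(phi))
        Tw[, q] <- solve(H, Tm[, q])
      }
    }
  }
  Tuse <- if (method == "MMASTOR") Tw else Tm
  if (is.null(sets)) {
    sets <- as.list(data$bim$id)
    names(sets) <- data$bim$id
  }
  rows <- lapply(names(sets), function(sid) {
    snps <- sets[[sid]]
    cols <- match(snps, colnames(data$X))
    if (anyNA(cols)) stop("unknown marker id(s) in set ", sid)
    Xs <- data$X[, cols, drop = FALSE]
    obs <- which(stats::complete.cases(Xs))
    res <- if (length(obs) == nrow(Xs)) {
      mfqls_test(Tuse, phi, Xs, method = method)
    } else {
      mfqls_test_missing(Tuse, phi, Xs[obs, , drop = FALSE], obs,
                         method = method)
    }
    data.frame(SET_ID = sid, CHR = data$bim$chr[cols[1L]],
               SNP_LIST = paste(snps, collapse = ","),
               M = length(snps), Q = ncol(Y), METHOD = method,
               STAT = res$statistic, DF = res$df, P = res$p_value,
               POS = data$bim$pos[cols[1L]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$CHR, out$POS), , drop = FALSE]
  rownames(out) <- NULL
  out[, setdiff(names(out), "POS")]
}

#' Write / read a result table
#'
#' Plain TSV with one row per tested variant set.
#'
#' @param results data frame from [run_scan].
#' @param path output file.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
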