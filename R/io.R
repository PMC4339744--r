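#' Read and write PLINK binary genotype filesets
#'
#' Minimal PLINK 1.9 `.bed`/`.bim`/`.fam` support.  The `.bed` parser
#' expects the SNP-major magic bytes (`0x6c 0x1b 0x01`) and decodes the
#' 2-bit codes to A1-allele counts (`00 -> 2`, `10 -> 1`, `11 -> 0`,
#' `01 -> NA`); A1 is taken as the minor (counted) allele unless
#' `keep_allele_order = FALSE` triggers re-orientation to the observed
#' minor allele.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param keep_allele_order count the A1 allele as written in the `.bim`
#'   (default); otherwise flip columns whose A1 frequency exceeds 0.5.
#' @return `read_plink`: list with `X` (`N x M` dosage matrix, rownames
#'   `fid:iid`, colnames marker ids), `fam` (a [pedigree]), `bim`
#'   (data frame: chr, id, cm, pos, a1, a2), `flipped` (logical per
#'   marker).
#' @export
read_plink <- function(prefix, keep_allele_order = TRUE) {
  fam <- read_fam(paste0(prefix, ".fam"))
  bim <- read_bim(paste0(prefix, ".bim"))
  n <- nrow(fam)
  m <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file: bad magic bytes")
  bpm <- ceiling(n / 4)
  raw <- readBin(con, "raw", bpm * m)
  if (length(raw) < bpm * m) stop("truncated .bed file")
  codes <- matrix(0L, 4L * bpm, m)
  ints <- matrix(as.integer(raw), bpm, m)
  for (k in 0:3) {
    codes[seq.int(k + 1L, by = 4L, length.out = bpm), ] <-
      ints %/% 4L^k %% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 2-bit code -> dosage of A1
  lut <- c(2L, NA_integer_, 1L, 0L)      # 00, 01, 10, 11
  X <- matrix(lut[codes + 1L], n, m)
  flipped <- rep(FALSE, m)
  if (!keep_allele_order) {
    f <- colMeans(X, na.rm = TRUE) / 2
    flipped <- !is.na(f) & f > 0.5
    X[, flipped] <- 2L - X[, flipped]
  }
  dimnames(X) <- list(paste(fam$fid, fam$iid, sep = ":"), bim$id)
  list(X = X, fam = fam, bim = bim, flipped = flipped)
}

#' @rdname read_plink
#' @param X dosage matrix to write (`NA` allowed).
#' @param fam a [pedigree] (phenotype column written as -9).
#' @param bim marker table (data frame with columns chr, id, cm, pos,
#'   a1, a2); defaults are synthesized from `colnames(X)`.
#' @export
write_plink <- function(prefix, X, fam, bim = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- ncol(X)
  if (is.null(bim))
    bim <- data.frame(chr = 1L, id = colnames(X) %||% paste0("snp", 1:m),
                      cm = 0, pos = seq_len(m), a1 = "A", a2 = "G")
  write_fam(fam, paste0(prefix, ".fam"))
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bpm <- ceiling(n / 4)
  # dosage -> 2-bit code (00 hom A1, 10 het, 11 hom A2, 01 missing)
  code <- matrix(1L, 4L * bpm, m)        # pad/missing = 01
  lut <- c(3L, 2L, 0L)                   # dosage 0, 1, 2
  v <- X + 1L
  cd <- matrix(lut[v], n, m)
  cd[is.na(cd)] <- 1L
  code[seq_len(n), ] <- cd
  weights <- 4L^(0:3)
  bytes <- matrix(0L, bpm, m)
  for (k in 0:3)
    bytes <- bytes + code[seq.int(k + 1L, by = 4L, length.out = bpm), ,
                          drop = FALSE] * weights[k + 1L]
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read and write PLINK text tables
#'
#' `.fam` files have columns FID, IID, PAT, MAT, SEX, PHENO (0 = missing
#' parent); `.bim` files have chr, id, cm, pos, a1, a2.  Phenotype and
#' covariate tables are whitespace-separated with a header whose first
#' two columns are FID and IID; the missing code defaults to `"NA"`.
#'
#' @param path file path.
#' @return `read_fam`: a [pedigree]; `read_bim`: a data frame;
#'   `read_pheno_table`: list with `ids` (fid:iid) and `values` (numeric
#'   matrix).
#' @export
read_fam <- function(path) {
  df <- utils::read.table(path, col.names = c("fid", "iid", "pat", "mat",
                                              "sex", "pheno"),
                          colClasses = c(rep("character", 4L),
                                         "integer", "numeric"))
  pedigree(fid = df$fid, iid = df$iid, father = df$pat, mother = df$mat,
           sex = df$sex)
}

#' @rdname read_fam
#' @param ped a [pedigree].
#' @export
write_fam <- function(ped, path) {
  df <- data.frame(fid = ped$fid, iid = ped$iid,
                   pat = ifelse(is.na(ped$father), "0", ped$father),
                   mat = ifelse(is.na(ped$mother), "0", ped$mother),
                   sex = ped$sex, pheno = -9)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_fam
#' @export
read_bim <- function(path) {
  utils::read.table(path, col.names = c("chr", "id", "cm", "pos",
                                        "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
}

#' @rdname read_fam
#' @param missing_code string treated as missing.
#' @export
read_pheno_table <- function(path, missing_code = "NA") {
  df <- utils::read.table(path, header = TRUE, na.strings = missing_code,
                          colClasses = "character",
                          check.names = FALSE)
  if (ncol(df) < 3L)
    stop("phenotype/covariate table needs FID, IID and >= 1 value column")
  ids <- paste(df[[1L]], df[[2L]], sep = ":")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "numeric"
  rownames(vals) <- ids
  list(ids = ids, values = vals)
}

#' Write a simulated dataset as a PLINK fileset plus phenotype table
#'
#' Exercises the file-based analysis path end to end: genotypes go to
#' `prefix.bed/.bim/.fam`, phenotypes (the dichotomized matrix when
#' present, else the quantitative one) to `prefix.pheno.tsv`, and, when a
#' null panel was simulated, the GRM to `prefix.grm.txt`.
#'
#' @param sim a `sim_dataset` from [simulate_dataset].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_sim_dataset <- function(sim, prefix) {
  X <- sim$X
  colnames(X) <- c("snpA", "snpB")
  bim <- data.frame(chr = 1L, id = colnames(X), cm = 0,
                    pos = c(1000L, 2000L), a1 = "A", a2 = "G")
  write_plink(prefix, X, sim$ped, bim)
  Y <- if (!is.null(sim$Yd)) sim$Yd else sim$Y
  colnames(Y) <- paste0("pheno", seq_len(ncol(Y)))
  df <- data.frame(FID = sim$ped$fid, IID = sim$ped$iid, Y,
                   check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".pheno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$null_panel)) {
    G <- grm_from_genotypes(sim$null_panel$X)
    write_grm(G, paste0(prefix, ".grm.txt"))
  }
  invisible(prefix)
}
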