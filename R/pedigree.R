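#' Pedigree objects
#'
#' A pedigree is a data frame of individuals with parent links, one row per
#' individual, following PLINK `.fam` conventions: `fid` (family id), `iid`
#' (individual id), `father`/`mother` (ids within the same family, `NA` for
#' founders), and `sex` (1 = male, 2 = female, 0 = unknown).  Ids must be
#' unique within a family, both parents must be either present or absent
#' (half-specified parentage is rejected), every named parent must exist in
#' the same family, and parent links must be acyclic.
#'
#' @param fid,iid character vectors of family and individual ids.
#' @param father,mother character vectors of parental ids; `NA` (or `"0"`)
#'   marks a founder.
#' @param sex integer vector in `{0, 1, 2}`; defaults to unknown.
#' @return An object of class `pedigree`: a data frame with columns
#'   `fid`, `iid`, `father`, `mother`, `sex` and `founder` (derived).
#' @examples
#' ped <- pedigree(fid = rep("f1", 3), iid = c("p1", "p2", "c1"),
#'                 father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"))
#' kinship_from_pedigree(ped)["f1:c1", "f1:p1"]  # 0.5
#' @export
pedigree <- function(fid, iid, father = NA, mother = NA, sex = 0L) {
  n <- length(iid)
  fid <- rep_len(as.character(fid), n)
  iid <- as.character(iid)
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  sex <- rep_len(as.integer(sex), n)
  father[!is.na(father) & father == "0"] <- NA_character_
  mother[!is.na(mother) & mother == "0"] <- NA_character_
  if (length(fid) != n || length(father) != n || length(mother) != n)
    stop("pedigree columns must have equal length")
  if (!all(sex %in% 0:2)) stop("sex must be coded 0 (unknown), 1, or 2")
  if (anyDuplicated(paste(fid, iid, sep = "\r")))
    stop("individual ids must be unique within family")
  half <- xor(is.na(father), is.na(mother))
  if (any(half))
    stop("half-specified parents for: ",
         paste(iid[half], collapse = ", "))
  ped <- data.frame(fid = fid, iid = iid, father = father, mother = mother,
                    sex = sex, founder = is.na(father) & is.na(mother),
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @rdname pedigree
#' @param ped a `pedigree` object.
#' @export
validate_pedigree <- function(ped) {
  for (f in unique(ped$fid)) {
    sub <- ped[ped$fid == f, , drop = FALSE]
    known <- sub$iid
    bad <- setdiff(stats::na.omit(c(sub$father, sub$mother)), known)
    if (length(bad))
      stop("unknown parent id(s) in family ", f, ": ",
           paste(unique(bad), collapse = ", "))
    # topological order existence <=> no ancestry cycle
    .pedigree_order(sub)
  }
  invisible(ped)
}

# Topological ordering (parents before children); errors on cycles.
# Returns row indices into `sub`.
.pedigree_order <- function(sub) {
  n <- nrow(sub)
  fa <- match(sub$father, sub$iid)
  mo <- match(sub$mother, sub$iid)
  placed <- logical(n)
  order <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    order <- c(order, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("cycle detected in pedigree of family ", sub$fid[1],
         " (individual(s) ", paste(sub$iid[!placed], collapse = ", "), ")")
  order
}

#' Canonical three-generation simulation pedigree
#'
#' The 10-member extended family used throughout the simulator: two
#' grandparents, two of their children each married to an unrelated founder
#' spouse, and two grandchildren per couple (4 founders' descendants across
#' three generations, 6 founders in total counting the spouses).
#'
#' @param n_families number of replicate families.
#' @return A [pedigree] with `10 * n_families` rows; family ids are
#'   `"fam1"`, `"fam2"`, ...
#' @export
canonical_pedigree <- function(n_families = 1L) {
  iid <- c("gp1", "gp2", "p1", "sp1", "p2", "sp2",
           "o11", "o12", "o21", "o22")
  father <- c(NA, NA, "gp1", NA, "gp1", NA,
              "p1", "p1", "sp2", "sp2")
  mother <- c(NA, NA, "gp2", NA, "gp2", NA,
              "sp1", "sp1", "p2", "p2")
  sex <- c(1L, 2L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L)
  fid <- rep(paste0("fam", seq_len(n_families)), each = 10L)
  pedigree(fid = fid, iid = rep(iid, n_families),
           father = rep(father, n_families),
           mother = rep(mother, n_families), sex = rep(sex, n_families))
}

#' Expected relationship matrix from a pedigree
#'
#' Computes the additive relationship matrix `Phi` with entries
#' `2 * pi_ab` off the diagonal (twice the kinship coefficient) and
#' `1 + d_a` on the diagonal (`d_a` the inbreeding coefficient), by the
#' standard recursion over a topological ordering: for founders
#' `pi_aa = 1/2`, between-founder kinship 0; for a child `c` of parents
#' `(f, m)`, `pi_cx = (pi_fx + pi_mx) / 2` for previously placed `x` and
#' `pi_cc = (1 + pi_fm) / 2`.  The result is block-diagonal across
#' families.
#'
#' @param ped a [pedigree].
#' @return A symmetric `N x N` relationship matrix with
#'   `dimnames = "fid:iid"` and attribute `source = "pedigree"`.
#' @export
kinship_from_pedigree <- function(ped) {
  validate_pedigree(ped)
  N <- nrow(ped)
  phi <- matrix(0, N, N)
  ids <- paste(ped$fid, ped$iid, sep = ":")
  dimnames(phi) <- list(ids, ids)
  for (f in unique(ped$fid)) {
    rows <- which(ped$fid == f)
    sub <- ped[rows, , drop = FALSE]
    ord <- .pedigree_order(sub)
    fa <- match(sub$father, sub$iid)
    mo <- match(sub$mother, sub$iid)
    n <- nrow(sub)
    K <- matrix(0, n, n)           # kinship coefficients pi
    placed <- integer(0)
    for (i in ord) {
      if (is.na(fa[i])) {
        K[i, i] <- 0.5
        # founder: unrelated to everyone placed so far
      } else {
        K[i, placed] <- (K[fa[i], placed] + K[mo[i], placed]) / 2
        K[placed, i] <- K[i, placed]
        K[i, i] <- (1 + K[fa[i], mo[i]]) / 2
      }
      placed <- c(placed, i)
    }
    phi[rows, rows] <- 2 * K
  }
  structure(phi, source = "pedigree")
}
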