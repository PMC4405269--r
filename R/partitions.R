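#' Enumerate alternative phenotype partitions
#'
#' A partition assigns each of the `d` phenotypes to one of three classes:
#' `"U"` (unassociated with the SNP), `"D"` (directly associated) or `"I"`
#' (indirectly associated, i.e. associated with the SNP but conditionally
#' independent of it given the directly associated phenotypes). The null
#' partition (all `"U"`) and assignments that place a phenotype in `"I"`
#' without any mediator in `"D"` are excluded, leaving `3^d - 2^d`
#' alternatives.
#'
#' @param d Number of phenotypes (1--14; the enumeration grows as `3^d`).
#' @return A character matrix with `3^d - 2^d` rows and `d` columns, each row
#'   a valid alternative partition, in lexicographic order over the codes
#'   `U < D < I` per phenotype.
#' @examples
#' enumerate_partitions(2)  # 5 alternatives
#' nrow(enumerate_partitions(3))  # 19
#' @seealso [partition_weight()], [mvbf()]
#' @export
enumerate_partitions <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d != round(d)) {
    stop("`d` must be a positive integer", call. = FALSE)
  }
  if (d > 14) {
    stop("d > 14: enumerating 3^d - 2^d partitions is impractical; ",
         "use the two-stage filter (`filter_scan()`) to reduce the phenotype ",
         "set or screen SNPs first", call. = FALSE)
  }
  codes <- c("U", "D", "I")
  grid <- as.matrix(expand.grid(rep(list(0:2), d), KEEP.OUT.ATTRS = FALSE))
  # lexicographic with phenotype 1 most significant
  grid <- grid[, rev(seq_len(d)), drop = FALSE]
  # valid alternatives are exactly the assignments with at least one D:
  # this drops the null (all U) and every I-without-mediator assignment,
  # leaving 3^d - 2^d rows
  keep <- rowSums(grid == 1L) > 0L
  grid <- grid[keep, , drop = FALSE]
  ord <- do.call(order, as.data.frame(grid))
  grid <- grid[ord, , drop = FALSE]
  out <- matrix(codes[grid + 1L], nrow = nrow(grid), ncol = d,
                dimnames = list(NULL, paste0("Y", seq_len(d))))
  out
}

validate_partition <- function(partition, d = length(partition)) {
  partition <- as.character(partition)
  if (length(partition) != d) {
    stop("partition length does not match the number of phenotypes", call. = FALSE)
  }
  if (!all(partition %in% c("U", "D", "I"))) {
    stop('partition entries must be "U", "D" or "I"', call. = FALSE)
  }
  if (!any(partition == "D")) {
    if (any(partition == "I")) {
      stop("invalid partition: indirect association requires at least one ",
           "directly associated phenotype", call. = FALSE)
    }
    stop("the all-U partition is the null model, not a valid alternative",
         call. = FALSE)
  }
  partition
}

#' Prior weight of a phenotype partition
#'
#' Default prior over alternative partitions: uniform on the number of
#' associated phenotypes `A = |D| + |I|` over `1..d`; given `A`, uniform on
#' `|D|` over `1..A`; given `(A, |D|)`, uniform over the
#' `choose(d, A) * choose(A, |D|)` concrete assignments. The weights of all
#' alternatives sum to exactly 1.
#'
#' @param partition Character vector of length `d` over `"U"`, `"D"`, `"I"`;
#'   must be a valid alternative (see [enumerate_partitions()]).
#' @param d Number of phenotypes; defaults to `length(partition)`.
#' @return The prior weight, a single number in (0, 1].
#' @examples
#' partition_weight(c("D", "D"))  # 1/4
#' partition_weight(c("D", "I"))  # 1/8
#' @export
partition_weight <- function(partition, d = length(partition)) {
  partition <- validate_partition(partition, d)
  A <- sum(partition != "U")
  nD <- sum(partition == "D")
  1 / (d * A * choose(d, A) * choose(A, nD))
}

# vectorized weights for an enumeration matrix, in log
log_partition_weights <- function(partitions) {
  d <- ncol(partitions)
  A <- rowSums(partitions != "U")
  nD <- rowSums(partitions == "D")
  -(log(d) + log(A) + lchoose(d, A) + lchoose(A, nD))
}
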