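#' Hill-number diversity
#'
#' Effective number of phylotypes per sample, `qD = (sum_i p_i^q)^(1/(1-q))`
#' with `p_i` the relative abundance of OTU i. Zero-abundance OTUs are
#' excluded from the sum. `q = 1` is handled by its limit
#' `exp(-sum p log p)`; `q = 2` (the default used throughout the pipeline) is
#' the inverse Simpson concentration `1 / sum p^2`.
#'
#' @param m samples x OTUs matrix of relative abundances. Rows are
#'   renormalized to sum to 1 (counts are accepted).
#' @param q order of diversity, `q >= 0`.
#' @return named numeric vector of per-sample diversities. Values lie in
#'   `[1, S]` where S is the number of OTUs present.
#' @export
#' @examples
#' hillDiversity(rbind(a = c(0.25, 0.25, 0.25, 0.25),
#'                     b = c(0.2, 0.2, 0.3, 0.3)), q = 2)
hillDiversity <- function(m, q = 2) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("relative abundances must be non-negative")
  if (q < 0) stop("q must be >= 0")
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("all-zero sample row(s): ",
         paste((rownames(m) %||% seq_len(nrow(m)))[tot == 0], collapse = ", "))
  p <- m / tot
  vals <- apply(p, 1, function(r) {
    r <- r[r > 0]
    if (abs(q - 1) < 1e-12) exp(-sum(r * log(r)))
    else sum(r^q)^(1 / (1 - q))
  })
  names(vals) <- rownames(m)
  vals
}
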