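# Stratified randomization for the two-arm dose comparison.

#' Stratified permuted-block randomization
#'
#' Assigns each participant to the 15- or 30-minute dose arm using permuted
#' blocks within strata defined by the four binary stratification factors:
#' site, sex assigned at birth, prior mindfulness experience (3+ sessions),
#' and current treatment. The 1:1 allocation is balanced within each
#' stratum up to the block tolerance.
#'
#' @param strata data frame with columns `site`, `sex`, `prior_mindfulness`,
#'   `current_treatment` (any atomic values; each defines a factor level).
#'   Missing values are a contract error.
#' @param block_size permuted-block length (default 2, i.e. pairs).
#' @param seed integer RNG seed.
#' @return the input as a tibble with an added `arm` column
#'   (`"min15"` / `"min30"`), rows in input order.
#' @export
randomize <- function(strata, block_size = 2L, seed = 1L) {
  need <- c("site", "sex", "prior_mindfulness", "current_treatment")
  miss <- setdiff(need, names(strata))
  if (length(miss)) {
    stop_npda(paste("strata missing columns:", paste(miss, collapse = ", ")),
              "npda_contract_error")
  }
  if (anyNA(strata[need])) {
    stop_npda("incomplete stratification data", "npda_contract_error")
  }
  stopifnot(block_size >= 2, block_size %% 2 == 0)
  strata <- tibble::as_tibble(strata)
  key <- do.call(paste, c(strata[need], sep = "|"))
  arm <- character(nrow(strata))
  with_seed(seed, {
    for (k in sort(unique(key))) {
      idx <- which(key == k)
      n_blocks <- ceiling(length(idx) / block_size)
      seq_arms <- unlist(lapply(seq_len(n_blocks), function(b) {
        sample(rep(c("min15", "min30"), block_size / 2))
      }))
      arm[idx] <- seq_arms[seq_along(idx)]
    }
  })
  strata$arm <- arm
  strata
}
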