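# Degenerate draws (every draw identical) let path-arithmetic identities be
# checked exactly against hand-computed products and sums.
degenerate_draws <- function(values, iter = 10, chains = 2) {
  a <- array(rep(unlist(values), each = iter * chains),
             c(iter, chains, length(values)),
             dimnames = list(NULL, NULL, names(values)))
  new_draws(a)
}

rdsem_fit_stub <- function(values) {
  structure(list(draws = degenerate_draws(values), hatch_direct = FALSE),
            class = "climpaths_rdsem")
}

msem_fit_stub <- function(values, nests = NULL) {
  structure(
    list(draws = degenerate_draws(values), hatch_direct = FALSE,
         spec = list(nests = nests)),
    class = "climpaths_msem"
  )
}

toy_counts <- function() {
  tibble::tibble(
    year = 1941:1945,
    boxes_surveyed = c(110, 100, 113, 120, 120),
    boxes_focal = c(50, 0, 47, 60, 60),
    boxes_parid = c(10, 0, 13, 20, 20),
    population_label = "a"
  )
}

small_config <- function(seed = 1, ...) {
  generator_config(n_years = 20, nests_per_year = 12, seed = seed, ...)
}
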