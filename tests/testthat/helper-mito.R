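# Shared fixtures: everything is generated in code at test time.

canonical <- mito_params()

# a feasible random state inside the invariant box (Wee1/Cdc25 site pairs
# sum below their totals; pENSA:B55 complex does not exceed total pENSA)
random_box_state <- function(params = canonical) {
  upper <- c(params[["SubTot"]], params[["CycBTot"]], params[["PP1Tot"]],
             params[["ENSATot"]], params[["GwlTot"]], params[["B55Tot"]],
             1, 1, 1, 1)
  u <- stats::runif(10) * upper
  u[7:8] <- u[7:8] / sum(u[7:8]) * stats::runif(1)
  u[9:10] <- u[9:10] / sum(u[9:10]) * stats::runif(1)
  u[4] <- max(u[4], params[["B55Tot"]] - u[6] + 0.01)
  mito_state(stats::setNames(u, names(interphase_state(params))))
}

# small population / grid used by the cheaper unit tests
small_pop <- population_spec(n_quantiles = 16)

# memoised store for expensive shared computations inside one test run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}
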