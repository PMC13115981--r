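# Shared fixtures built in code.

# small cohort profile for fast stochastic tests
tiny_profile <- function(n = 500, p_female = 0.5627) {
  prof <- cohort_profile()
  prof$n_total <- n
  prof$p_female <- p_female
  prof
}

# base case is expensive enough to share within a test file
base_case_cached <- local({
  bc <- NULL
  function() {
    if (is.null(bc)) bc <<- run_base_case()
    bc
  }
})

# individual-level microsimulation through the same per-cycle matrices:
# independent oracle for the cohort recursion
microsim <- function(model, arm, n = 2e5, n_cycles = 10, init_state = 1,
                     seed = 42) {
  set.seed(seed)
  p <- build_cycle_matrix(model, arm, 0)
  cum <- t(apply(p, 1, cumsum))
  state <- rep.int(init_state, n)
  mace_entries <- 0; deaths <- 0
  for (t in seq_len(n_cycles)) {
    alive <- state != 6L
    u <- stats::runif(sum(alive))
    cur <- state[alive]
    nxt <- integer(length(cur))
    for (s in unique(cur)) {
      idx <- cur == s
      nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    mace_entries <- mace_entries + sum(cur %in% 1:3 & nxt == 4L)
    deaths <- deaths + sum(nxt == 6L)
    state[alive] <- nxt
  }
  list(mace = mace_entries, deaths = deaths, n = n)
}
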