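# Thin backend interface for mixed-integer linear programs.
#
# Cardinality matching needs an exact MILP solver. The default engine is
# HiGHS, reached through the scientific Python runtime (scipy.optimize.milp)
# via reticulate. The interface is deliberately minimal so another engine
# can be dropped in.

.milp_env <- new.env(parent = emptyenv())

milp_modules <- function() {
  if (!is.null(.milp_env$sp)) return(.milp_env)
  ok <- requireNamespace("reticulate", quietly = TRUE)
  if (ok) {
    # pin the interpreter to the one on PATH before reticulate initializes;
    # otherwise discovery may fail on systems without a registered python
    if (Sys.getenv("RETICULATE_PYTHON") == "" &&
        !reticulate::py_available(initialize = FALSE)) {
      py <- Sys.which("python3")
      if (py == "") py <- Sys.which("python")
      if (py != "") Sys.setenv(RETICULATE_PYTHON = py)
    }
    ok <- tryCatch({
      .milp_env$sp <- reticulate::import("scipy.optimize")
      .milp_env$np <- reticulate::import("numpy")
      TRUE
    }, error = function(e) FALSE)
  }
  if (!ok) {
    stop_no_call("no mixed-integer solver available: cardinality matching ",
                 "requires a MILP backend")
  }
  .milp_env
}

# Maximize obj'x subject to con_lower <= A x <= con_upper,
# 0 <= x <= upper, x integer. Returns list(x, objective, status, gap).
solve_milp_max <- function(obj, A, con_lower, con_upper, upper,
                           time_limit = NULL, rel_gap = 0) {
  m <- milp_modules()
  n <- length(obj)
  opts <- list(presolve = TRUE)
  if (!is.null(time_limit)) opts$time_limit <- as.numeric(time_limit)
  if (!is.null(rel_gap) && rel_gap > 0) opts$mip_rel_gap <- as.numeric(rel_gap)
  res <- m$sp$milp(
    c = -as.numeric(obj),
    constraints = m$sp$LinearConstraint(A, as.numeric(con_lower),
                                        as.numeric(con_upper)),
    integrality = m$np$array(rep(1L, n)),
    bounds = m$sp$Bounds(rep(0, n), as.numeric(upper)),
    options = opts
  )
  status <- c("optimal", "limit_reached", "infeasible", "unbounded",
              "numerical")[res$status + 1L]
  x <- if (!is.null(res$x)) round(as.numeric(res$x)) else NULL
  list(x = x,
       objective = if (!is.null(x)) sum(obj * x) else NA_real_,
       status = status,
       gap = res$mip_gap %||% NA_real_)
}
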