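# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the LP oracle enumerates polytope vertices, the
# rule oracle evaluates the tree the generator built (not a parsed string).

# Maximum of obj'v over {v : S v = 0, lb <= v <= ub} by brute-force vertex
# enumeration. Only sensible for a handful of reactions.
vertex_enum_lp <- function(S, lb, ub, obj, tol = 1e-9) {
  n <- ncol(S)
  rk <- qr(S)$rank
  k <- n - rk                      # bounds active at a vertex
  best <- -Inf
  feasible <- FALSE
  if (k == 0) {
    cand <- list(integer(0))
  } else {
    cand <- utils::combn(n, k, simplify = FALSE)
  }
  for (fixed in cand) {
    free <- setdiff(seq_len(n), fixed)
    sides <- expand.grid(rep(list(c("lb", "ub")), length(fixed)),
                         stringsAsFactors = FALSE)
    if (length(fixed) == 0) sides <- data.frame(row.names = 1)
    for (si in seq_len(nrow(sides))) {
      v <- rep(NA_real_, n)
      if (length(fixed) > 0) {
        side <- unlist(sides[si, ], use.names = FALSE)
        v[fixed] <- ifelse(side == "lb", lb[fixed], ub[fixed])
      }
      if (length(free) > 0) {
        A <- S[, free, drop = FALSE]
        b <- if (length(fixed) > 0) {
          -S[, fixed, drop = FALSE] %*% v[fixed]
        } else {
          rep(0, nrow(S))
        }
        if (qr(A)$rank < length(free)) next
        sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
        if (is.null(sol)) next
        v[free] <- sol
      }
      if (max(abs(S %*% v)) > tol * max(1, max(abs(ub)))) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      feasible <- TRUE
      best <- max(best, sum(obj * v))
    }
  }
  if (!feasible) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}

# Random GPR tree paired with its own evaluator (independent of parse_gpr /
# minsum). Returns list(string, value_fun(abundance)).
random_gpr_tree <- function(genes, depth = 0, max_depth = 4) {
  if (depth >= max_depth || stats::runif(1) < 0.35) {
    g <- sample(genes, 1)
    return(list(
      string = g,
      leaves = g,
      eval = function(ab) if (g %in% names(ab)) ab[[g]] else 0
    ))
  }
  op <- sample(c("and", "or"), 1)
  n_kids <- sample(2:3, 1)
  kids <- lapply(seq_len(n_kids), function(i) {
    random_gpr_tree(genes, depth + 1, max_depth)
  })
  list(
    string = paste0("(", paste(vapply(kids, `[[`, "", "string"),
                               collapse = paste0(" ", op, " ")), ")"),
    leaves = unlist(lapply(kids, `[[`, "leaves")),
    eval = function(ab) {
      vals <- vapply(kids, function(kid) kid$eval(ab), 0)
      if (op == "and") min(vals) else sum(vals)
    }
  )
}

# Tiny annotation table for rule-level imputation tests.
tiny_annotation <- function() {
  validate_annotation(tibble::tibble(
    gene_id = c("A1", "A2", "A3", "B1", "B2", "C1"),
    localization = "Cytosol",
    function_level1 = c("ClassA", "ClassA", "ClassA", "ClassB", "ClassB",
                        "ClassC"),
    function_level2 = c("L2_1", "L2_1", "L2_1", "L2_1", "L2_1", "L2_2"),
    cofactor = c("ATP", "ATP", "none", "GTP", "none", "none"),
    hpa_category = c("Detected in all", "Detected in some", "Not detected",
                     "Detected in many", "#N/A", "Detected in all"),
    kcat = c(10, NA, 5, 20, NA, 1)
  ))
}

toy_medium <- function() {
  tibble::tibble(metabolite_id = c("glc_e", "gln_e"), mM = c(25, 4))
}
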