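# Shared fixtures: the bundled vitamin D model, hand-built literal trees
# and a brute-force path-enumeration oracle independent of rollback().

vitd_model <- function() read_cea_model(example_model_path())

# Literal (parameter-free) versions of the two arms, built from the
# published inputs, for tree tests that bypass the config layer.
depression_subtree <- function(p_dep) {
  chance_node(list(
    list(p = p_dep, node = terminal_node(335.4, 0.545,
                                         outcome = "depression")),
    list(p = 1 - p_dep, node = terminal_node(0, 0.76,
                                             outcome = "healthy"))),
    label = "depression incidence")
}

noint_strategy <- function() {
  strategy("no intervention", chance_node(list(
    list(p = 0.76, node = depression_subtree(0.314)),
    list(p = 0.24, node = depression_subtree(0.16))),
    label = "vitamin D status"))
}

supp_strategy <- function() {
  strategy("supplementation", chance_node(list(
    list(p = 0.172, node = depression_subtree(0.314)),
    list(p = 0.828, node = depression_subtree(0.16))),
    label = "vitamin D status"), upfront_cost = 0.604)
}

# Random valid strategy with literal payoffs, depth <= max_depth.
random_strategy <- function(max_depth = 4) {
  build <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.35)
      return(terminal_node(stats::runif(1, 0, 500), stats::runif(1),
                           outcome = sample(c("depression", "healthy"),
                                            1)))
    k <- sample(2:3, 1)
    w <- stats::rgamma(k, shape = 1) + 1e-6
    p <- w / sum(w)
    chance_node(lapply(seq_len(k), function(i)
      list(p = p[i], node = build(depth - 1))))
  }
  root <- build(max_depth)
  if (root$kind == "terminal")
    root <- chance_node(list(list(p = 0.5, node = root),
                             list(p = 0.5, node = build(1))))
  strategy("random", root, upfront_cost = stats::runif(1, 0, 10))
}

# Oracle: explicit enumeration of all root-to-leaf paths. Only handles
# literal probabilities/payoffs, keeping it independent of the package's
# parameter-resolution machinery.
enumerate_paths <- function(strat) {
  rows <- list()
  walk <- function(node, prob) {
    if (node$kind == "terminal") {
      rows[[length(rows) + 1L]] <<- data.frame(
        prob = prob, cost = node$cost, utility = node$utility,
        outcome = if (is.null(node$outcome)) NA_character_
                  else node$outcome)
      return(invisible())
    }
    for (b in node$branches) walk(b$node, prob * b$p)
  }
  walk(strat$root, 1)
  do.call(rbind, rows)
}

brute_force_ev <- function(strat) {
  paths <- enumerate_paths(strat)
  list(cost = strat$upfront_cost + sum(paths$prob * paths$cost),
       effect = sum(paths$prob * paths$utility),
       total_prob = sum(paths$prob))
}
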