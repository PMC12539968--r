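# Fixtures built in code: a small hand-written colony, focal-record
# builders, and random multiplex generators for the PageRank oracles.

# six-animal demography: two egos (E1 2016 cohort, E2 2017), a shared
# matriline, one over-age alter, one removable alter
tiny_demography <- function() {
  data.frame(
    animal_id = c("M1", "M2", "E1", "E2", "A1", "A2", "A3"),
    sex = c("F", "F", "F", "M", "F", "M", "F"),
    birth_date = as.Date(c("2008-03-01", "2009-05-01", "2016-04-15",
                           "2017-05-10", "2016-06-01", "2013-04-01",
                           "2012-07-01")),
    matriline_id = c("MA", "MB", "MA", "MB", "MA", "MB", "MB"),
    mother_id = c(NA, NA, "M1", "M2", "M1", NA, NA),
    removal_date = as.Date(c(NA, NA, NA, NA, NA, "2018-06-15", NA)),
    cohort = c("other", "other", "2016", "2017", "other", "other", "other"),
    stringsAsFactors = FALSE)
}

# focal record rows with defaults, one call per record
focal_row <- function(focal = "E1", date = "2016-07-01", session = 0L,
                      interval = 0L, behaviour = "proximity",
                      partner = "A1", direction = "undirected") {
  data.frame(focal_id = focal, session_date = date,
             session_index = session, interval_index = interval,
             behaviour = behaviour, partner_id = partner,
             direction = direction, stringsAsFactors = FALSE)
}

tiny_bouts <- function() {
  data.frame(
    winner_id = c("M1", "M1", "M2", "M1", "M2", "A3"),
    loser_id = c("M2", "A3", "A3", "M2", "A3", "M2"),
    date = as.Date(c("2016-02-01", "2016-03-01", "2016-04-01",
                     "2017-02-01", "2017-03-01", "2017-04-01")),
    stringsAsFactors = FALSE)
}

# star unilayer network built directly (bypassing binning)
star_net <- function(ego = "E1", behaviour = "proximity", month = 1,
                     alters = c("A1", "A2"), weights = c(1, 1),
                     directions = NULL) {
  if (is.null(directions)) {
    directions <- rep(if (behaviour %in% DIRECTED_BEHAVIOURS) "given"
                      else "undirected", length(alters))
  }
  unilayer_ego_network(ego, behaviour, month,
                       data.frame(alter_id = alters, direction = directions,
                                  weight = weights,
                                  stringsAsFactors = FALSE))
}

# multilayer network from a list of (alters, weights, directions) per layer
star_multilayer <- function(ego = "E1", behaviour = "proximity",
                            partition = 1, layers = list()) {
  nets <- lapply(seq_along(layers), function(l) {
    ly <- layers[[l]]
    if (length(ly$alters) == 0) {
      unilayer_ego_network(ego, behaviour, l,
                           data.frame(alter_id = character(),
                                      direction = character(),
                                      weight = numeric()))
    } else {
      star_net(ego, behaviour, l, ly$alters, ly$weights, ly$directions)
    }
  })
  alters <- unique(unlist(lapply(nets, function(n) n$edges$alter_id)))
  structure(list(ego_id = ego, behaviour = behaviour,
                 partition_index = partition, layers = nets,
                 node_set = c(ego, sort(alters))),
            class = "multilayer_ego_network")
}

# random star multiplex for the eigen-oracle: <= max_nodes alters,
# <= max_layers layers, random weights, directed or undirected
random_multiplex <- function(max_nodes = 9, max_layers = 4,
                             directed = NA) {
  behaviour <- if (isTRUE(directed)) "groom" else
    if (isFALSE(directed)) "proximity" else
      sample(c("groom", "proximity"), 1)
  n_alt <- sample(2:max_nodes, 1)
  L <- sample(1:max_layers, 1)
  alters <- sprintf("A%02d", seq_len(n_alt))
  layers <- lapply(seq_len(L), function(l) {
    k <- sample(0:n_alt, 1)
    if (k == 0) return(list(alters = character()))
    sel <- sample(alters, k)
    if (behaviour %in% DIRECTED_BEHAVIOURS) {
      dirs <- sample(c("given", "received"), k, TRUE)
    } else dirs <- rep("undirected", k)
    list(alters = sel, weights = sample(1:9, k, TRUE), directions = dirs)
  })
  star_multilayer("EGO", behaviour, 1, layers)
}

# dense left-eigenvector oracle for the stationary distribution
eigen_stationary <- function(supra) {
  e <- eigen(t(supra$transition))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# brute-force per-row reference for the joint log-likelihood
reference_loglik <- function(table, params, spec = model_spec()) {
  X <- multiego:::build_design(table, spec)
  total <- 0
  for (i in seq_len(nrow(table))) {
    eta <- numeric(7)
    for (c in 1:7) {
      eta[c] <- sum(X[i, ] * params$beta[, c]) +
        params$u[as.character(table$ego_id[i]), c] +
        params$v[as.character(table$alter_id[i]), c]
    }
    pb <- function(x) 1 / (1 + exp(-x))
    bern <- function(y, p) if (y == 1) log(p) else log(1 - p)
    hlnorm <- function(y, hu, mu, s) {
      if (y == 0) log(hu) else {
        log(1 - hu) + dnorm(log(y), mu, s, log = TRUE) - log(y)
      }
    }
    total <- total + bern(table$aggr_bin[i], pb(eta[1])) +
      bern(table$groom_bin[i], pb(eta[2])) +
      bern(table$play_bin[i], pb(eta[3])) +
      hlnorm(table$contact_vers[i], pb(eta[4]), eta[5],
             params$sigma_contact) +
      hlnorm(table$proximity_vers[i], pb(eta[6]), eta[7],
             params$sigma_proximity)
  }
  total
}

# small scaled model table + truth for fit smoke tests
small_recovery_data <- function(n_ego = 20, n_alter = 60,
                                alters_per_ego = 20, seed = 1,
                                re_sd = 0.4, beta_range = c(-1, 1)) {
  skel <- model_table_skeleton(n_ego, n_alter, alters_per_ego, seed = seed)
  X <- multiego:::build_design(skel, model_spec())
  truth <- random_truth(colnames(X), seed = seed + 1,
                        beta_range = beta_range, re_sd = re_sd)
  tab <- simulate_from_model(skel, truth, seed = seed + 2)
  list(table = tab, truth = truth, skeleton = skel)
}
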