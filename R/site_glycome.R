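## Site-specific glycome network smoothing: a graph over glycan compositions
## (edges = single monosaccharide addition/removal), biosynthetic neighborhood
## membership weights, and a Laplacian-regularized fit that spreads observed
## glycan evidence to biosynthetically related compositions as a prior credit
## u_g. Decoy peptides and decoy glycans resolve to the same u_g as their
## target counterparts by construction.

#' Build the glycome graph over a composition list
#'
#' Nodes are glycan compositions; an undirected edge joins two compositions
#' whose monosaccharide counts differ by exactly one residue (L1 distance 1).
#'
#' @param glycans list of [glycan_composition()] objects.
#' @return list(nodes = canonical strings, counts = matrix, adjacency,
#'   laplacian).
#' @export
build_graph <- function(glycans) {
  stopifnot(length(glycans) >= 1L)
  nodes <- vapply(glycans, format, character(1))
  monos <- .MONOSACCHARIDES$name
  counts <- t(vapply(glycans, function(g) {
    v <- stats::setNames(integer(length(monos)), monos)
    v[names(g$counts)] <- g$counts
    v
  }, integer(length(monos))))
  rownames(counts) <- nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (n > 1L) {
    d <- as.matrix(stats::dist(counts, method = "manhattan"))
    A[d == 1] <- 1
  }
  D <- diag(rowSums(A), n)
  list(nodes = nodes, counts = counts, adjacency = A, laplacian = D - A)
}

#' Default N-glycan biosynthetic neighborhoods
#'
#' Nine rule-based neighborhoods defined as per-monosaccharide count
#' intervals (high-mannose, paucimannose, hybrid, bi/tri/tetra-antennary,
#' fucosylated, sialylated, fucosylated-sialylated). Membership weights are
#' trapezoidal: 1 inside every interval, 0.5 at count distance 1 outside one
#' interval, 0 beyond.
#'
#' @return named list of constraint lists `list(mono = c(lo, hi))`.
#' @export
default_neighborhoods <- function() {
  list(
    `high-mannose` = list(HexNAc = c(2, 2), Hex = c(4, 9), NeuAc = c(0, 0),
                          dHex = c(0, 0)),
    paucimannose = list(HexNAc = c(2, 2), Hex = c(0, 3), NeuAc = c(0, 0)),
    hybrid = list(HexNAc = c(3, 3), Hex = c(4, 7)),
    biantennary = list(HexNAc = c(4, 4), Hex = c(3, 5)),
    triantennary = list(HexNAc = c(5, 5), Hex = c(4, 6)),
    tetraantennary = list(HexNAc = c(6, 7), Hex = c(5, 8)),
    fucosylated = list(dHex = c(1, 4), NeuAc = c(0, 0)),
    sialylated = list(NeuAc = c(1, 4), dHex = c(0, 0)),
    `fucosylated-sialylated` = list(NeuAc = c(1, 4), dHex = c(1, 4))
  )
}

#' Read a neighborhood definition file
#'
#' Text format, one neighborhood per line:
#' `name<TAB>Mono=lo-hi;Mono=lo-hi;...`; `#` comments allowed.
#'
#' @param path file path.
#' @return named list of constraint lists.
#' @export
read_neighborhoods <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) != 2L) stop("malformed neighborhood line: ", ln)
    rules <- strsplit(parts[2], ";")[[1]]
    cons <- list()
    for (r in rules) {
      kv <- strsplit(trimws(r), "=")[[1]]
      rng <- as.numeric(strsplit(kv[2], "-")[[1]])
      if (length(rng) == 1L) rng <- c(rng, rng)
      cons[[trimws(kv[1])]] <- rng
    }
    out[[parts[1]]] <- cons
  }
  out
}

trapezoid_weight <- function(x, lo, hi) {
  if (x >= lo && x <= hi) 1
  else if (x == lo - 1 || x == hi + 1) 0.5
  else 0
}

#' Neighborhood membership matrix A
#'
#' @param graph a [build_graph()] result.
#' @param neighborhoods constraint lists (default [default_neighborhoods()]).
#' @return glycan x neighborhood weight matrix with entries in `[0, 1]`.
#' @export
membership_matrix <- function(graph, neighborhoods = default_neighborhoods()) {
  A <- matrix(0, nrow(graph$counts), length(neighborhoods),
              dimnames = list(graph$nodes, names(neighborhoods)))
  for (j in seq_along(neighborhoods)) {
    cons <- neighborhoods[[j]]
    for (i in seq_len(nrow(graph$counts))) {
      w <- 1
      for (m in names(cons)) {
        x <- if (m %in% colnames(graph$counts)) graph$counts[i, m] else 0
        w <- w * trapezoid_weight(x, cons[[m]][1], cons[[m]][2])
        if (w == 0) break
      }
      A[i, j] <- w
    }
  }
  A
}

## Solve the smoothing objective for a fixed lambda:
##   min_{u, tau}  sum_obs (y_g - u_g)^2 + lambda * (u' L u + ||u - A tau||^2)
## by block coordinate descent (both blocks are linear solves). lambda scales
## both regularizers so that lambda = 0 returns the observations untouched.
solve_site_objective <- function(y, observed, L, A, lambda,
                                 tol = 1e-8, max_iter = 200L) {
  n <- length(y)
  S <- diag(as.numeric(observed), n)
  if (lambda == 0) {
    u <- ifelse(observed, y, 0)
    tau <- drop(qr.coef(qr(A), u))
    tau[is.na(tau)] <- 0
    return(list(u = u, tau = tau))
  }
  u <- ifelse(observed, y, 0)
  tau <- rep(0, ncol(A))
  M <- S + lambda * L + lambda * diag(n)
  qa <- qr(A)
  for (it in seq_len(max_iter)) {
    u_new <- drop(solve(M, as.numeric(observed) * y + lambda * drop(A %*% tau)))
    tau_new <- drop(qr.coef(qa, u_new))
    tau_new[is.na(tau_new)] <- 0
    delta <- max(abs(u_new - u), if (length(tau)) abs(tau_new - tau) else 0)
    u <- u_new; tau <- tau_new
    if (delta < tol * max(1, max(abs(u)))) break
  }
  list(u = u, tau = tau)
}

#' Fit a site-specific glycome smoothing model
#'
#' Observed per-glycan scores at one glycosite are spread over the glycome
#' graph by a Laplacian penalty and pulled toward neighborhood regression
#' values `A tau`. The smoothing weight lambda is chosen by
#' leave-one-observation-out error over a grid capped at 0.2 to prevent
#' over-smoothing; inferred priors are clipped at 0.
#'
#' @param observations named numeric vector: canonical composition string ->
#'   observed glycan score (> 0). Callers should restrict to confident
#'   identifications (e.g. joint FDR <= 1%).
#' @param graph a [build_graph()] over the site's glycome search space.
#' @param neighborhoods constraint lists.
#' @param lambda_grid candidate smoothing weights (values above 0.2 are
#'   dropped).
#' @param site site identifier (e.g. "PROT1:123").
#' @return a `site_glycome_model`: list(site, tau, lambda, u) with `u` a named
#'   vector of per-glycan priors, 0 for glycans outside the graph.
#' @export
fit_site_model <- function(observations, graph,
                           neighborhoods = default_neighborhoods(),
                           lambda_grid = seq(0, 0.2, by = 0.025),
                           site = "site") {
  lambda_grid <- lambda_grid[lambda_grid <= 0.2]
  if (length(observations) == 0L || all(observations <= 0)) {
    return(structure(list(site = site, tau = NULL, lambda = NA_real_,
                          u = stats::setNames(rep(0, length(graph$nodes)),
                                              graph$nodes)),
                     class = "site_glycome_model"))
  }
  observations <- observations[observations > 0]
  A <- membership_matrix(graph, neighborhoods)
  n <- length(graph$nodes)
  y <- stats::setNames(rep(0, n), graph$nodes)
  obs_in <- intersect(names(observations), graph$nodes)
  y[obs_in] <- observations[obs_in]
  ## normalize observed scores to [0, y_max] per site (scores already >= 0;
  ## keep the scale so u_g lands in score units)
  observed <- graph$nodes %in% obs_in
  pick_lambda <- function() {
    if (sum(observed) < 2L || length(lambda_grid) == 1L)
      return(lambda_grid[1])
    err <- vapply(lambda_grid, function(l) {
      e <- 0
      for (o in which(observed)) {
        obs2 <- observed; obs2[o] <- FALSE
        fit <- solve_site_objective(y * as.numeric(obs2), obs2,
                                    graph$laplacian, A, l)
        e <- e + (fit$u[o] - y[o])^2
      }
      e
    }, numeric(1))
    lambda_grid[which.min(err)]
  }
  lambda <- pick_lambda()
  fit <- solve_site_objective(y, observed, graph$laplacian, A, lambda)
  u <- pmax(fit$u, 0)
  names(u) <- graph$nodes
  structure(list(site = site, tau = stats::setNames(fit$tau, colnames(A)),
                 lambda = lambda, u = u),
            class = "site_glycome_model")
}

#' Site-glycome prior u_g for a candidate glycan
#'
#' Decoy glycans receive the same value as their target counterpart, and
#' decoy peptides resolve through the mirrored site registry to the target
#' site's model: the smoothing pathway cannot distinguish targets from
#' decoys. Unmodeled sites or glycans return 0.
#'
#' @param models named list of `site_glycome_model`s keyed by target site id.
#' @param site site id; for decoy peptides pass the mapped target site id
#'   via `decoy_site_map`.
#' @param glycan a [glycan_composition()] or canonical string.
#' @param decoy_site_map optional named map decoy site id -> target site id.
#' @return u_g >= 0.
#' @export
u_for <- function(models, site, glycan, decoy_site_map = NULL) {
  if (!is.null(decoy_site_map) && site %in% names(decoy_site_map))
    site <- decoy_site_map[[site]]
  model <- models[[site]]
  if (is.null(model)) return(0)
  key <- if (inherits(glycan, "glycan_composition")) format(glycan) else glycan
  v <- model$u[key]
  if (is.na(v)) 0 else as.numeric(v)
}

#' Serialize site models to JSON
#' @param models named list of site models. @param path output file.
#' @export
write_site_models <- function(models, path) {
  jsonlite::write_json(
    lapply(models, function(m)
      list(site = m$site, tau = as.list(m$tau), lambda = m$lambda,
           u = as.list(m$u))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read site models written by [write_site_models()]
#' @param path model JSON file.
#' @return named list of `site_glycome_model`s.
#' @export
read_site_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    structure(list(site = m$site, tau = unlist(m$tau),
                   lambda = if (is.null(m$lambda)) NA_real_ else m$lambda,
                   u = unlist(m$u)),
              class = "site_glycome_model")
  })
}
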