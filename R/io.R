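# Model / scenario / result input-output.

#' Serialize a community model to JSON
#'
#' Dense row-major matrices, bounds as affine piece lists; the inverse
#' of [read_community_json()].
#'
#' @param model a [community_model()].
#' @param path output file path.
#' @export
write_community_json <- function(model, path) {
  doc <- list(
    extracellular_ids = model$extracellular_ids,
    species = lapply(model$species, function(sp) list(
      id = sp$id,
      metabolite_ids = sp$metabolite_ids,
      reaction_ids = sp$reaction_ids,
      S = as.vector(t(sp$S)),
      A = as.vector(t(sp$A)),
      T = as.vector(t(sp$T)),
      growth_index = sp$growth_index,
      uptake_rows = sp$uptake_rows,
      bounds = lapply(sp$b, function(b) lapply(b$pieces, function(p)
        list(intercept = p$intercept, gradient = p$gradient)))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a community model from JSON
#' @param path file written by [write_community_json()].
#' @return a [community_model()].
#' @export
read_community_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ext <- vapply(doc$extracellular_ids, as.character, "")
  species <- lapply(doc$species, function(sp) {
    n_nu <- length(sp$reaction_ids)
    met <- vapply(sp$metabolite_ids, as.character, "")
    rxn <- vapply(sp$reaction_ids, as.character, "")
    S <- matrix(unlist(sp$S), ncol = n_nu, byrow = TRUE,
                dimnames = list(met, rxn))
    A <- matrix(unlist(sp$A), ncol = n_nu, byrow = TRUE)
    T <- matrix(unlist(sp$T), ncol = n_nu, byrow = TRUE,
                dimnames = list(ext, rxn))
    b <- lapply(sp$bounds, function(pieces) bound_spec(lapply(pieces,
      function(p) list(intercept = p$intercept, gradient = unlist(p$gradient)))))
    species_network(sp$id, met, rxn, S, A, b, T,
                    growth_index = sp$growth_index,
                    uptake_rows = unlist(sp$uptake_rows))
  })
  community_model(species, ext)
}

#' Read a scenario configuration (YAML or JSON)
#'
#' A scenario file names the model (a built-in fixture or a JSON model
#' file), the environment, and optional solver settings. Unknown keys
#' are rejected.
#'
#' Schema:
#' \preformatted{
#' model:
#'   builtin: pd_network | coexistence_network |
#'            synthetic_syntrophic_pair | random_community
#'   args: {...}            # passed to the fixture constructor
#'   # or: json: path/to/model.json
#' environment:
#'   mode: CA | CC | BA | BC
#'   D: 0.5                 # chemostat modes
#'   C_in: [10, 0, 0]       # chemostat modes
#'   u: [10, 0, 0]          # batch modes
#'   objective: biomass_production | sum_growth   # community modes
#' solver:                  # all optional
#'   seed: 1
#'   omega: 100
#'   time_limit: 60
#'   threshold: 1.0e-8
#'   grid: {lower: [0,0], upper: [1,1], points: 5}
#' }
#'
#' @param config_path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with `model` ([community_model()]), `env`
#'   ([environment_spec()]) and `settings` (named list of solver
#'   settings with defaults filled in).
#' @export
read_scenario <- function(config_path) {
  cfg <- if (grepl("\\.ya?ml$", config_path)) {
    yaml::read_yaml(config_path)
  } else {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  }
  known_top <- c("model", "environment", "solver")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) stop("unknown configuration keys: ",
                          paste(extra, collapse = ", "))
  if (is.null(cfg$model)) stop("missing key: model")
  if (is.null(cfg$environment)) stop("missing key: environment")
  envc <- cfg$environment
  extra <- setdiff(names(envc), c("mode", "D", "C_in", "u", "objective"))
  if (length(extra)) stop("unknown environment keys: ",
                          paste(extra, collapse = ", "))
  if (is.null(envc$mode)) stop("missing key: environment$mode")

  model <- if (!is.null(cfg$model$builtin)) {
    builders <- list(pd_network = pd_network,
                     coexistence_network = coexistence_network,
                     synthetic_syntrophic_pair = synthetic_syntrophic_pair,
                     random_community = random_community)
    fn <- builders[[cfg$model$builtin]]
    if (is.null(fn)) stop("unknown builtin model: ", cfg$model$builtin)
    do.call(fn, if (is.null(cfg$model$args)) list() else as.list(cfg$model$args))
  } else if (!is.null(cfg$model$json)) {
    read_community_json(cfg$model$json)
  } else stop("model must give either 'builtin' or 'json'")

  env <- environment_spec(envc$mode,
                          D = envc$D,
                          C_in = if (!is.null(envc$C_in)) as.numeric(unlist(envc$C_in)),
                          u = if (!is.null(envc$u)) as.numeric(unlist(envc$u)),
                          objective = envc$objective)
  settings <- list(seed = 1L, omega = NULL, time_limit = 60,
                   threshold = 1e-8, grid = NULL)
  if (!is.null(cfg$solver)) {
    extra <- setdiff(names(cfg$solver), names(settings))
    if (length(extra)) stop("unknown solver keys: ",
                            paste(extra, collapse = ", "))
    settings[names(cfg$solver)] <- cfg$solver
  }
  if (is.null(settings$omega) && env$mode %in% c("CA", "CC")) {
    settings$omega <- choose_omega(model, env)
  }
  list(model = model, env = env, settings = settings)
}

solution_order <- function(sols) {
  if (length(sols) <= 1L) return(seq_along(sols))
  ab <- do.call(rbind, lapply(sols, function(s)
    if (!is.null(s$X)) s$X else s$x))
  do.call(order, as.data.frame(ab))
}

#' Write accepted solutions to CSV or JSON
#'
#' CSV: one row per (solution, species), with flux columns `nu.<rxn>`,
#' concentration columns `C.<compound>`, the abundance, the maximal
#' residual and a branch label. JSON: the full nested structure
#' including multipliers. Ordering is deterministic (abundance vectors,
#' lexicographic).
#'
#' @param sols list of [steady_state_solution()] objects.
#' @param out_path output file.
#' @param format `"csv"` or `"json"`.
#' @param model the [community_model()] the solutions refer to
#'   (column naming).
#' @export
write_solutions <- function(sols, out_path, format = c("csv", "json"),
                            model = NULL) {
  format <- match.arg(format)
  sols <- sols[solution_order(sols)]
  if (format == "json") {
    named <- function(v) if (is.null(v)) NULL else as.list(v)
    doc <- lapply(seq_along(sols), function(k) {
      s <- sols[[k]]
      list(solution = k, nu = lapply(s$nu, named), C = named(s$C),
           X = named(s$X), x = named(s$x),
           mu_star = s$mu_star, lambda1 = s$lambda1, lambda2 = s$lambda2,
           residual_max = s$residual_max, residual_ssq = s$residual_ssq,
           branch = if (!is.null(s$branch))
             list(delta = s$branch$delta, support = s$branch$support))
    })
    # 17 significant digits: doubles survive the round trip bit-exactly
    jsonlite::write_json(doc, out_path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    return(invisible(out_path))
  }
  rows <- list()
  for (k in seq_along(sols)) {
    s <- sols[[k]]
    ab <- if (!is.null(s$X)) s$X else s$x
    for (i in seq_along(s$nu)) {
      row <- list(solution = k, species = names(s$nu)[i],
                  abundance = unname(ab[i]))
      nu <- s$nu[[i]]
      names(nu) <- paste0("nu.", names(nu))
      row <- c(row, as.list(nu))
      if (!is.null(s$C)) {
        Cv <- s$C; names(Cv) <- paste0("C.", names(Cv))
        row <- c(row, as.list(Cv))
      }
      if (!is.null(s$mu_star)) row$mu_star <- s$mu_star
      row$residual_max <- s$residual_max
      row$branch <- if (!is.null(s$branch))
        paste(s$branch$support, collapse = "") else NA_character_
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- if (length(rows)) do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE))) else
      data.frame(solution = integer(0), species = character(0),
                 abundance = numeric(0), residual_max = numeric(0))
  utils::write.csv(df, out_path, row.names = FALSE)
  invisible(out_path)
}

#' Read solutions back from the JSON form
#' @param path file written by [write_solutions()] with
#'   `format = "json"`.
#' @return list of [steady_state_solution()] objects.
#' @export
read_solutions_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc, function(d) {
    num <- function(v) if (is.null(v)) NULL else {
      out <- vapply(v, as.numeric, 0)
      if (!is.null(names(v))) names(out) <- names(v)
      out
    }
    steady_state_solution(
      nu = lapply(d$nu, num),
      C = num(d$C), X = num(d$X), x = num(d$x),
      mu_star = if (!is.null(d$mu_star)) as.numeric(d$mu_star),
      lambda1 = num(d$lambda1), lambda2 = num(d$lambda2),
      residual_max = as.numeric(d$residual_max),
      residual_ssq = as.numeric(d$residual_ssq),
      branch = if (!is.null(d$branch))
        complementarity_pattern(unlist(d$branch$delta),
                                unlist(d$branch$support)))
  })
}
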