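# Built-in example communities and environment sweeps.

#' Prisoner's-dilemma crossfeeding community
#'
#' Two symmetric species fed on a single substrate S. Each species can
#' convert intracellular S into compounds A and B, needs one unit of each
#' to grow, and produces one of the two at half the yield of its partner:
#' species 1 pays two units of S per unit of A (`r_A: 2 S_c -> A_c`) but
#' only one per unit of B, species 2 mirrored. Transporters for A and B
#' are bidirectional, so mutual secretion (crossfeeding) raises the
#' community yield while unilateral defection raises an individual's.
#'
#' With `kinetic_bounds = TRUE` the uptake fluxes are capped by the
#' extracellular concentrations (`nu_tS <= C_S` etc.), the form needed by
#' the chemostat modes. With `FALSE` only irreversibility constraints
#' remain, the form required by the batch modes.
#'
#' @param kinetic_bounds include concentration-dependent uptake bounds.
#' @return a [community_model()] with species `sp1`, `sp2`, extracellular
#'   compounds `S_e`, `A_e`, `B_e`.
#' @export
pd_network <- function(kinetic_bounds = TRUE) {
  rxn <- c("t_S", "t_A", "t_B", "r_A", "r_B", "mu")
  met <- c("S_c", "A_c", "B_c")
  ext <- c("S_e", "A_e", "B_e")
  make_sp <- function(id, yield_A, yield_B) {
    S <- matrix(0, 3, 6, dimnames = list(met, rxn))
    S["S_c", "t_S"] <- 1
    S["A_c", "t_A"] <- 1
    S["B_c", "t_B"] <- 1
    S["S_c", "r_A"] <- -yield_A; S["A_c", "r_A"] <- 1
    S["S_c", "r_B"] <- -yield_B; S["B_c", "r_B"] <- 1
    S["A_c", "mu"] <- -1; S["B_c", "mu"] <- -1
    T <- matrix(0, 3, 6, dimnames = list(ext, rxn))
    T["S_e", "t_S"] <- 1
    T["A_e", "t_A"] <- 1
    T["B_e", "t_B"] <- 1
    irrev <- c("t_S", "r_A", "r_B", "mu")
    if (kinetic_bounds) {
      A <- matrix(0, 7, 6, dimnames = list(NULL, rxn))
      A[1, "t_S"] <- 1; A[2, "t_A"] <- 1; A[3, "t_B"] <- 1
      for (k in seq_along(irrev)) A[3 + k, irrev[k]] <- -1
      e <- function(j) { g <- rep(0, 3); g[j] <- 1; g }
      b <- c(lapply(1:3, function(j) bound_spec(list(list(intercept = 0, gradient = e(j))))),
             lapply(1:4, function(k) constant_bound(0, 3)))
      uptake <- 1:3
    } else {
      A <- matrix(0, 4, 6, dimnames = list(NULL, rxn))
      for (k in seq_along(irrev)) A[k, irrev[k]] <- -1
      b <- lapply(1:4, function(k) constant_bound(0, 3))
      uptake <- integer(0)
    }
    species_network(id, met, rxn, S, A, b, T, growth_index = 6L,
                    uptake_rows = uptake)
  }
  community_model(list(make_sp("sp1", 2, 1), make_sp("sp2", 1, 2)), ext)
}

#' Two-nutrient coexistence community
#'
#' Two species that both require the externally supplied compounds A and
#' B to grow, with asymmetric demands: species 1 consumes `a1` units of A
#' and `b1` of B per unit growth, species 2 `a2` and `b2`, with
#' `a1 > b1` and `b2 > a2`. Transporters are uptake-only, so crossfeeding
#' is impossible and any coexistence arises from differential nutrient
#' limitation.
#'
#' @param a1,b1,a2,b2 growth stoichiometries (defaults 2,1,1,2).
#' @param bound_type `"concentration"` for chemostat-style uptake caps
#'   `nu_t <= 2 C` or `"constant"` for batch-style caps `nu_t <= 2`.
#' @return a [community_model()] with extracellular compounds
#'   `A_e`, `B_e`.
#' @export
coexistence_network <- function(a1 = 2, b1 = 1, a2 = 1, b2 = 2,
                                bound_type = c("concentration", "constant")) {
  bound_type <- match.arg(bound_type)
  if (!(a1 > b1 && b1 >= 0)) stop("need a1 > b1 >= 0")
  if (!(b2 > a2 && a2 >= 0)) stop("need b2 > a2 >= 0")
  rxn <- c("t_A", "t_B", "mu")
  met <- c("A_c", "B_c")
  ext <- c("A_e", "B_e")
  make_sp <- function(id, a, b) {
    S <- matrix(0, 2, 3, dimnames = list(met, rxn))
    S["A_c", "t_A"] <- 1
    S["B_c", "t_B"] <- 1
    S["A_c", "mu"] <- -a; S["B_c", "mu"] <- -b
    T <- matrix(0, 2, 3, dimnames = list(ext, rxn))
    T["A_e", "t_A"] <- 1
    T["B_e", "t_B"] <- 1
    A <- matrix(0, 5, 3, dimnames = list(NULL, rxn))
    A[1, "t_A"] <- 1; A[2, "t_B"] <- 1
    A[3, "t_A"] <- -1; A[4, "t_B"] <- -1; A[5, "mu"] <- -1
    if (bound_type == "concentration") {
      b_list <- list(bound_spec(list(list(intercept = 0, gradient = c(2, 0)))),
                     bound_spec(list(list(intercept = 0, gradient = c(0, 2)))))
      uptake <- 1:2
    } else {
      b_list <- list(constant_bound(2, 2), constant_bound(2, 2))
      uptake <- integer(0)
    }
    b_list <- c(b_list, lapply(1:3, function(k) constant_bound(0, 2)))
    species_network(id, met, rxn, S, A, b_list, T, growth_index = 3L,
                    uptake_rows = uptake)
  }
  community_model(list(make_sp("sp1", a1, b1), make_sp("sp2", a2, b2)), ext)
}

#' Seeded random community generator
#'
#' Generates reproducible random communities for property testing. Every
#' species has uptake transporters feeding a chain of internal
#' conversions ending in the growth substrate, so `S nu = 0` always has a
#' non-trivial feasible cone and the growth reaction is producible from
#' the exchanged compounds. Transporters are uptake-only with bounds
#' equal to the corresponding concentration; all reactions irreversible.
#'
#' @param seed integer seed (restores the caller's RNG state on exit).
#' @param n_species,n_internal,n_exchange sizes (all >= 1).
#' @return a [community_model()].
#' @export
random_community <- function(seed, n_species = 2, n_internal = 3,
                             n_exchange = 2) {
  stopifnot(n_species >= 1, n_internal >= 1, n_exchange >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ext <- paste0("E", seq_len(n_exchange))
  make_sp <- function(i) {
    met <- paste0("M", seq_len(n_internal))
    n_conv <- max(0L, n_internal - 1L)
    rxn <- c(paste0("t", seq_len(n_exchange)),
             if (n_conv) paste0("conv", seq_len(n_conv)), "mu")
    n_nu <- length(rxn)
    S <- matrix(0, n_internal, n_nu, dimnames = list(met, rxn))
    T <- matrix(0, n_exchange, n_nu, dimnames = list(ext, rxn))
    for (j in seq_len(n_exchange)) {
      tgt <- 1L + (j - 1L) %% n_internal
      S[tgt, j] <- 1
      T[j, j] <- 1
    }
    if (n_conv) for (k in seq_len(n_conv)) {
      S[k, n_exchange + k] <- -sample(1:2, 1)
      S[k + 1L, n_exchange + k] <- 1
    }
    S[n_internal, n_nu] <- -stats::runif(1, 0.5, 2)
    A <- -diag(1, n_nu) # all reactions irreversible
    b <- lapply(seq_len(n_nu), function(k) constant_bound(0, n_exchange))
    # uptake caps nu_tj <= C_j
    Acap <- matrix(0, n_exchange, n_nu)
    for (j in seq_len(n_exchange)) Acap[j, j] <- 1
    bcap <- lapply(seq_len(n_exchange), function(j) {
      g <- rep(0, n_exchange); g[j] <- 1
      bound_spec(list(list(intercept = 0, gradient = g)))
    })
    species_network(paste0("sp", i), met, rxn, S, rbind(Acap, A), c(bcap, b),
                    T, growth_index = n_nu, uptake_rows = seq_len(n_exchange))
  }
  community_model(lapply(seq_len(n_species), make_sp), ext)
}

#' Linear environment sweep
#'
#' Interpolates the inflow concentrations (chemostat modes) or the
#' culture uptake bounds (batch modes) linearly between two endpoints,
#' keeping every other field of the base environment fixed.
#'
#' @param base_env an [environment_spec()].
#' @param start_vector,end_vector endpoint vectors for `C_in` or `u`.
#' @param n number of environments (>= 2), endpoints included.
#' @return list of [environment_spec()] objects.
#' @export
sweep_environments <- function(base_env, start_vector, end_vector, n) {
  stopifnot(n >= 2)
  if (length(start_vector) != length(end_vector))
    stop("start and end vectors differ in length")
  chemostat <- base_env$mode %in% c("CA", "CC")
  ref <- if (chemostat) base_env$C_in else base_env$u
  if (length(start_vector) != length(ref))
    stop("sweep vector length does not match the environment")
  lapply(seq_len(n), function(k) {
    t <- (k - 1) / (n - 1)
    v <- (1 - t) * start_vector + t * end_vector
    env <- base_env
    if (chemostat) env$C_in <- v else env$u <- v
    env
  })
}

#' Minimal synthetic auxotroph-pair community
#'
#' A small, fully synthetic stand-in for an amino-acid syntrophic pair:
#' two species consume glucose `G` and require two "amino acid" compounds
#' `P` and `Q` for growth; each species can synthesise exactly one of the
#' two from glucose (`paux` lacks P synthesis, `qaux` lacks Q synthesis).
#' Because growth is limited by the crossfed compounds rather than by
#' glucose, the rational-agent chemostat model admits a band of
#' coexistence states fed by wasteful glucose allocation, while the
#' rational-community model selects isolated states. This fixture is a
#' synthetic construction for testing that qualitative behaviour; it is
#' not derived from any genome-scale model.
#'
#' @param a amino-acid requirement per unit growth.
#' @param k uptake kinetic constant (`nu_t <= k * C`).
#' @return a [community_model()] with extracellular compounds
#'   `G_e`, `P_e`, `Q_e`.
#' @seealso [synthetic_syntrophic_env()]
#' @export
synthetic_syntrophic_pair <- function(a = 0.5, k = 1) {
  rxn <- c("t_G", "t_P", "t_Q", "syn", "mu")
  met <- c("G_c", "P_c", "Q_c")
  ext <- c("G_e", "P_e", "Q_e")
  make_sp <- function(id, makes) { # makes: "P" or "Q"
    S <- matrix(0, 3, 5, dimnames = list(met, rxn))
    S["G_c", "t_G"] <- 1
    S["P_c", "t_P"] <- 1
    S["Q_c", "t_Q"] <- 1
    S["G_c", "syn"] <- -1
    S[paste0(makes, "_c"), "syn"] <- 1
    S["G_c", "mu"] <- -1; S["P_c", "mu"] <- -a; S["Q_c", "mu"] <- -a
    T <- matrix(0, 3, 5, dimnames = list(ext, rxn))
    T["G_e", "t_G"] <- 1; T["P_e", "t_P"] <- 1; T["Q_e", "t_Q"] <- 1
    A <- matrix(0, 6, 5, dimnames = list(NULL, rxn))
    A[1, "t_G"] <- 1; A[2, "t_P"] <- 1; A[3, "t_Q"] <- 1
    A[4, "t_G"] <- -1; A[5, "syn"] <- -1; A[6, "mu"] <- -1
    e <- function(j) { g <- rep(0, 3); g[j] <- k; g }
    b <- c(lapply(1:3, function(j) bound_spec(list(list(intercept = 0, gradient = e(j))))),
           lapply(1:3, function(j) constant_bound(0, 3)))
    species_network(id, met, rxn, S, A, b, T, growth_index = 5L,
                    uptake_rows = 1:3)
  }
  community_model(list(make_sp("paux", "Q"), make_sp("qaux", "P")), ext)
}

#' Default chemostat environment for the synthetic auxotroph pair
#'
#' Glucose in excess, trace supplements of both required compounds, slow
#' dilution; the regime in which the crossfed compounds, not the energy
#' source, limit growth.
#'
#' @param mode `"CA"` or `"CC"`.
#' @param D dilution rate.
#' @param supplement supplement concentration of each required compound.
#' @return an [environment_spec()].
#' @export
synthetic_syntrophic_env <- function(mode = c("CA", "CC"), D = 0.1,
                                     supplement = 0.2) {
  mode <- match.arg(mode)
  environment_spec(mode, D = D, C_in = c(10, supplement, supplement))
}
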