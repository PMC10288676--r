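# SBML (Level 3, FBC flux bounds) ingestion via xml2.
#
# No SBML parser package ships with this toolchain, and only a small
# subset of the standard is needed here: species, reactions with
# stoichiometry, and constant flux bounds. Extracellular species are
# moved out of the stoichiometric matrix into the exchange map T with
# an uptake-positive sign; pure exchange reactions (sources/sinks of
# extracellular species) are dropped, since the community environment
# supplies and removes compounds instead.

#' Read one species' network from an SBML file
#'
#' @param path SBML Level 3 file with `fbc` flux bounds.
#' @param exchange_tag regular expression identifying extracellular
#'   species by id (default: a `_e` suffix, BIGG style).
#' @param exchange_reaction_pattern reactions matching this pattern are
#'   treated as environment exchanges and dropped.
#' @param growth_pattern regular expression locating the growth
#'   (biomass) reaction; an error names the pattern when nothing
#'   matches.
#' @param id species identifier for the returned network.
#' @param inf_bound flux bounds with absolute value at or above this
#'   are treated as absent.
#' @return a [species_network()] whose `T` rows follow the order of the
#'   extracellular species encountered (attribute
#'   `extracellular_ids`).
#' @export
read_sbml_species <- function(path, exchange_tag = "_e$",
                              exchange_reaction_pattern = "^(R_)?EX_",
                              growth_pattern = "BIOMASS|[Bb]iomass",
                              id = "strain", inf_bound = 1000) {
  if (!file.exists(path)) {
    stop(structure(list(message = paste0("SBML file not found: ", path),
                        call = NULL),
                   class = c("commsteady_missing_file", "error",
                             "condition")))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  strip <- function(x) sub("^.*:", "", x)

  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  is_ext <- grepl(exchange_tag, sp_ids)
  met_ids <- sp_ids[!is_ext & !boundary]
  ext_ids <- sp_ids[is_ext & !boundary]

  par_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  keep <- !grepl(exchange_reaction_pattern, rx_ids)
  rx_nodes <- rx_nodes[keep]; rx_ids <- rx_ids[keep]
  n_nu <- length(rx_ids)
  if (!n_nu) stop("no reactions found in ", path)

  S <- matrix(0, length(met_ids), n_nu, dimnames = list(met_ids, rx_ids))
  T <- matrix(0, length(ext_ids), n_nu, dimnames = list(ext_ids, rx_ids))
  lb <- rep(-Inf, n_nu); ub <- rep(Inf, n_nu)
  for (k in seq_len(n_nu)) {
    node <- rx_nodes[[k]]
    add <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(st)) st <- 1
        if (sid %in% met_ids) S[sid, k] <<- S[sid, k] + sign * st
        else if (sid %in% ext_ids) T[sid, k] <<- T[sid, k] - sign * st
      }
    }
    add(".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']", -1)
    add(".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']", +1)
    lbref <- xml2::xml_attr(node, "lowerFluxBound")
    ubref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(par_val)) lb[k] <- par_val[[lbref]]
    if (!is.na(ubref) && ubref %in% names(par_val)) ub[k] <- par_val[[ubref]]
    if (is.na(lbref) && !isTRUE(xml2::xml_attr(node, "reversible") == "true"))
      lb[k] <- 0
  }
  lb[abs(lb) >= inf_bound] <- -Inf
  ub[abs(ub) >= inf_bound] <- Inf

  g_idx <- grep(growth_pattern, rx_ids)
  if (!length(g_idx)) stop("no growth reaction matches pattern '",
                           growth_pattern, "' in ", path)
  g_idx <- g_idx[1L]

  rows <- list(); b <- list()
  n_C <- length(ext_ids)
  for (k in seq_len(n_nu)) {
    if (is.finite(ub[k])) {
      r <- numeric(n_nu); r[k] <- 1
      rows[[length(rows) + 1L]] <- r
      b[[length(b) + 1L]] <- constant_bound(ub[k], n_C)
    }
    if (is.finite(lb[k])) {
      r <- numeric(n_nu); r[k] <- -1
      rows[[length(rows) + 1L]] <- r
      b[[length(b) + 1L]] <- constant_bound(-lb[k], n_C)
    }
  }
  A <- do.call(rbind, rows)
  out <- species_network(id, met_ids, rx_ids, S, A, b, T,
                         growth_index = g_idx, uptake_rows = integer(0))
  attr(out, "extracellular_ids") <- ext_ids
  out
}

#' Two-strain amino acid auxotroph community from an SBML base model
#'
#' Builds an auxotroph-pair community from a single base metabolic
#' model: one strain loses the synthesis route for one amino acid, the
#' partner for another, and an extra synthesis reaction plus uptake
#' kinetics are supplied through `params`. The base model file and all
#' quantitative parameters are caller-provided; nothing is bundled.
#'
#' @param sbml_path SBML file of the base model.
#' @param params named list with required fields:
#'   \describe{
#'     \item{extra_reaction}{`NULL` or list `id`, `stoichiometry`
#'       (named vector over metabolite/extracellular ids) added to both
#'       strains before the knockouts.}
#'     \item{knockout_a, knockout_b}{character vectors of reaction ids
#'       removed from strain A / strain B.}
#'     \item{uptake_kinetics}{named list: extracellular compound id ->
#'       list of affine pieces `list(intercept=, slope=)`, giving the
#'       concentration-dependent uptake cap of the matching transport
#'       flux (applied to every reaction consuming that compound).}
#'     \item{D}{dilution rate (default 0.1).}
#'     \item{C_in}{named inflow concentrations over the extracellular
#'       compounds (missing entries 0).}
#'   }
#' @param ... passed to [read_sbml_species()].
#' @return list with `model` (a [community_model()]) and `env`
#'   (a `"CA"` [environment_spec()]; switch `mode` as needed).
#' @export
syntrophic_pair <- function(sbml_path, params, ...) {
  required <- c("extra_reaction", "knockout_a", "knockout_b",
                "uptake_kinetics", "D", "C_in")
  missing <- setdiff(required, names(params))
  if (length(missing)) stop("params missing fields: ",
                            paste(missing, collapse = ", "))
  base <- read_sbml_species(sbml_path, id = "base", ...)
  ext_ids <- attr(base, "extracellular_ids")
  n_C <- length(ext_ids)

  add_reaction <- function(sp, rx) {
    n_nu <- length(sp$reaction_ids) + 1L
    S <- cbind(sp$S, 0); T <- cbind(sp$T, 0)
    colnames(S)[n_nu] <- rx$id; colnames(T)[n_nu] <- rx$id
    for (nm in names(rx$stoichiometry)) {
      if (nm %in% rownames(S)) S[nm, n_nu] <- rx$stoichiometry[[nm]]
      else if (nm %in% rownames(T)) T[nm, n_nu] <- -rx$stoichiometry[[nm]]
      else stop("unknown metabolite in extra reaction: ", nm)
    }
    A <- cbind(sp$A, 0)
    # irreversible by default
    r <- numeric(n_nu); r[n_nu] <- -1
    A <- rbind(A, r)
    b <- c(sp$b, list(constant_bound(0, n_C)))
    species_network(sp$id, rownames(S), colnames(S), S, A, b, T,
                    growth_index = sp$growth_index,
                    uptake_rows = sp$uptake_rows)
  }
  drop_reactions <- function(sp, ids) {
    keep <- !(sp$reaction_ids %in% ids)
    if (all(keep)) return(sp)
    if (!keep[sp$growth_index]) stop("cannot knock out the growth reaction")
    arows <- apply(abs(sp$A[, !keep, drop = FALSE]), 1L, sum) == 0
    species_network(sp$id, sp$metabolite_ids, sp$reaction_ids[keep],
                    sp$S[, keep, drop = FALSE],
                    sp$A[arows, keep, drop = FALSE],
                    sp$b[arows],
                    sp$T[, keep, drop = FALSE],
                    growth_index = sum(keep[seq_len(sp$growth_index)]),
                    uptake_rows = integer(0))
  }
  add_kinetics <- function(sp) {
    A <- sp$A; b <- sp$b; uptake <- sp$uptake_rows
    for (cmp in names(params$uptake_kinetics)) {
      ci <- match(cmp, ext_ids)
      if (is.na(ci)) stop("unknown extracellular compound: ", cmp)
      cols <- which(sp$T[ci, ] > 0)
      for (k in cols) {
        r <- numeric(ncol(A)); r[k] <- 1
        A <- rbind(A, r)
        pieces <- lapply(params$uptake_kinetics[[cmp]], function(p) {
          g <- rep(0, n_C); g[ci] <- p$slope
          list(intercept = p$intercept, gradient = g)
        })
        b <- c(b, list(bound_spec(pieces)))
        uptake <- c(uptake, nrow(A))
      }
    }
    species_network(sp$id, sp$metabolite_ids, sp$reaction_ids, sp$S, A, b,
                    sp$T, growth_index = sp$growth_index,
                    uptake_rows = uptake)
  }
  make_strain <- function(strain_id, ko) {
    sp <- base; sp$id <- strain_id
    if (!is.null(params$extra_reaction)) sp <- add_reaction(sp, params$extra_reaction)
    sp <- drop_reactions(sp, ko)
    add_kinetics(sp)
  }
  model <- community_model(list(make_strain("aux_a", params$knockout_a),
                                make_strain("aux_b", params$knockout_b)),
                           ext_ids)
  C_in <- rep(0, n_C)
  names(C_in) <- ext_ids
  if (length(params$C_in)) C_in[names(params$C_in)] <- unlist(params$C_in)
  D <- if (is.null(params$D)) 0.1 else params$D
  list(model = model, env = environment_spec("CA", D = D, C_in = unname(C_in)))
}
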