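# Energy engines: the pluggable level of theory behind the chemical reward.
# An engine is a list with fields `fidelity`, `evaluate` and optionally
# `optimize`. The evaluate contract depends on fidelity:
#   * "toy": evaluate(ctx) on an isomer context (pure graph function, no 3D)
#   * "forcefield": evaluate(geometry) -> MMFF94 energy in kcal/mol
#   * "tight-binding" / "external": subprocess adapters (never invoked in
#     tests; they raise EngineUnavailable when the executable is absent)

#' Construct an energy engine
#' @param fidelity One of "toy", "forcefield", "tight-binding", "external".
#' @param evaluate Function mapping input to an energy in kcal/mol.
#' @param optimize Optional geometry -> geometry relaxation.
#' @return An \code{energy_engine} object.
#' @export
energy_engine <- function(fidelity, evaluate, optimize = NULL) {
  stopifnot(is.function(evaluate))
  structure(list(fidelity = fidelity, evaluate = evaluate,
                 optimize = optimize), class = "energy_engine")
}

#' @export
print.energy_engine <- function(x, ...) {
  cat("<energy_engine>", x$fidelity, "\n"); invisible(x)
}

# ---------------------------------------------------------------------------
# Isomer context handed to toy engines: everything graph-computable about one
# isomer of a decoded state.

# subtree atoms + tree depths (bond distance from the beta carbon) of one
# substituent root in a parse
substituent_atoms <- function(parse, root) {
  n <- length(parse$elem)
  depth <- rep(NA_integer_, n)
  depth[root] <- 1L
  repeat {
    grew <- FALSE
    for (a in seq_len(n)) if (is.na(depth[a]) && parse$parent[a] != 0L &&
                              !is.na(depth[parse$parent[a]])) {
      depth[a] <- depth[parse$parent[a]] + 1L; grew <- TRUE
    }
    if (!grew) break
  }
  keep <- which(!is.na(depth))
  list(elem = parse$elem[keep], depth = depth[keep], atoms = keep)
}

# isomer contexts (E and Z) for a decoded state
isomer_contexts <- function(decoded) {
  p <- decoded$parse
  roots <- p$sub_roots
  s1 <- if (length(roots) >= 1L) substituent_atoms(p, roots[1L])
        else list(elem = character(0), depth = integer(0), atoms = integer(0))
  s2 <- if (length(roots) >= 2L) substituent_atoms(p, roots[2L])
        else list(elem = character(0), depth = integer(0), atoms = integer(0))
  nd <- sum(p$pbond == 2L); nt <- sum(p$pbond == 3L)
  mk <- function(iso) {
    # E puts the first-written substituent anti (trans) to the aryl group
    cis  <- if (iso == "E") s2 else s1
    trans <- if (iso == "E") s1 else s2
    list(isomer = iso, graph = decoded$graph, cis = cis, trans = trans,
         n_heavy = length(p$elem), n_double = nd, n_triple = nt)
  }
  list(E = mk("E"), Z = mk("Z"))
}

#' Toy energy engine over weighted substructure features
#'
#' A deterministic, side-effect-free pseudo-energy defined purely on the
#' molecular graph, so that complete bounded spaces are scorable in seconds
#' while exercising the full isomerization-gap machinery. The per-isomer
#' energy combines an isomer-asymmetric steric strain (substituent bulk syn
#' to the aryl group, weighted down with tree depth), an electronic
#' stabilization by the substituent anti to the aryl group, and
#' isomer-symmetric base terms:
#' \deqn{E = \sum_{a \in cis} w_s(a)/(1+d_a) - \sum_{a \in trans} w_e(a)/(1+d_a)
#'       + c_1 n_{heavy} + c_2 n_{=} - c_3 n_{\#}}
#'
#' @param steric Named weights (kcal/mol) per element for the syn side.
#' @param electronic Named weights per element for the anti side.
#' @param common Length-3 numeric: weights of heavy-atom count, double-bond
#'   count and triple-bond count (isomer-symmetric; they cancel in gaps).
#' @return An \code{energy_engine} with fidelity \code{"toy"}.
#' @examples
#' eng <- toy_engine()
#' d <- decode_to_smiles("CF")
#' ctx <- isomer_contexts(d)
#' eng$evaluate(ctx$E) - eng$evaluate(ctx$Z)   # E_E - E_Z
#' @export
toy_engine <- function(steric = c(C = 0.9, N = 0.75, O = 0.6, F = 0.45),
                       electronic = c(C = 0.1, N = 0.3, O = 0.5, F = 0.8),
                       common = c(0.15, 0.4, 0.25)) {
  force(steric); force(electronic); force(common)
  evaluate <- function(ctx) {
    need <- unique(c(ctx$cis$elem, ctx$trans$elem))
    if (!all(need %in% names(steric)) || !all(need %in% names(electronic)))
      stop("FormulaError: no weight for element(s) ",
           paste(setdiff(need, names(steric)), collapse = ","), call. = FALSE)
    s <- sum(steric[ctx$cis$elem] / (1 + ctx$cis$depth))
    e <- sum(electronic[ctx$trans$elem] / (1 + ctx$trans$depth))
    s - e + common[1] * ctx$n_heavy + common[2] * ctx$n_double -
      common[3] * ctx$n_triple
  }
  energy_engine("toy", evaluate)
}

#' MMFF94 force-field engine
#'
#' Evaluates the MMFF94 energy (kcal/mol) of a 3D geometry through the
#' Open Babel `obenergy` tool; `optimize` re-embeds and minimizes.
#'
#' @return An \code{energy_engine} with fidelity \code{"forcefield"}.
#' @export
forcefield_engine <- function() {
  evaluate <- function(geom) {
    if (Sys.which("obenergy") == "")
      stop("EngineUnavailable: obenergy not on PATH", call. = FALSE)
    tmp <- tempfile(fileext = ".xyz")
    on.exit(unlink(tmp))
    writeLines(write_xyz_text(geom), tmp)
    out <- suppressWarnings(
      system2("obenergy", c("-ff", "MMFF94", tmp), stdout = TRUE, stderr = FALSE))
    line <- grep("TOTAL ENERGY", out, value = TRUE)
    if (!length(line))
      stop("EngineUnavailable: MMFF94 evaluation failed", call. = FALSE)
    as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", line[length(line)]))
  }
  energy_engine("forcefield", evaluate,
                optimize = function(smiles) embed_and_preoptimize(smiles))
}

#' GFN2-xTB tight-binding adapter
#'
#' Subprocess contract for a semi-empirical geometry optimization stage.
#' The executable is optional: when absent, constructing is allowed but any
#' call raises an \code{EngineUnavailable} condition, and pipelines fall
#' back to force-field-only fidelity.
#'
#' @param path Path to the `xtb` executable.
#' @return An \code{energy_engine} with fidelity \code{"tight-binding"}.
#' @export
xtb_engine <- function(path = Sys.which("xtb")) {
  unavailable <- function(...) {
    stop(structure(class = c("EngineUnavailable", "error", "condition"),
                   list(message = "GFN2-xTB executable not available",
                        call = sys.call(-1))))
  }
  if (!nzchar(path) || !file.exists(path))
    return(energy_engine("tight-binding", unavailable, unavailable))
  run <- function(geom, args) {
    dir <- tempfile("xtb"); dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    xyz <- file.path(dir, "in.xyz")
    writeLines(write_xyz_text(geom), xyz)
    out <- system2(path, c(xyz, args), stdout = TRUE, stderr = FALSE)
    list(dir = dir, out = out)
  }
  evaluate <- function(geom) {
    res <- run(geom, "--gfn 2")
    line <- grep("TOTAL ENERGY", res$out, value = TRUE)
    if (!length(line)) unavailable()
    as.numeric(sub(".*?(-?[0-9.]+).*", "\\1", line[1])) * 627.5094740631
  }
  optimize <- function(geom) {
    res <- run(geom, c("--gfn", "2", "--opt"))
    opt <- file.path(res$dir, "xtbopt.xyz")
    if (!file.exists(opt)) unavailable()
    read_xyz_text(paste(readLines(opt), collapse = "\n"), "TB-optimized")
  }
  energy_engine("tight-binding", evaluate, optimize)
}

#' CREST conformer-sampling adapter
#'
#' Subprocess contract for metadynamics conformer search on top of an
#' optimized geometry; the sampling time is lengthened by
#' \code{mtmd_time_factor} relative to the tool default. Optional: when the
#' executable is absent any call raises \code{EngineUnavailable}; toy and
#' force-field fidelities skip this stage entirely.
#'
#' @param path Path to the `crest` executable.
#' @param mtmd_time_factor Multiplier on the default metadynamics time.
#' @return A function geometry -> lowest-energy conformer geometry.
#' @export
crest_sampler <- function(path = Sys.which("crest"), mtmd_time_factor = 3) {
  function(geom) {
    if (!nzchar(path) || !file.exists(path))
      stop(structure(class = c("EngineUnavailable", "error", "condition"),
                     list(message = "CREST executable not available",
                          call = sys.call(-1))))
    dir <- tempfile("crest"); dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    xyz <- file.path(dir, "in.xyz")
    writeLines(write_xyz_text(geom), xyz)
    system2(path, c(xyz, "--mdlen", sprintf("x%g", mtmd_time_factor)),
            stdout = FALSE, stderr = FALSE)
    best <- file.path(dir, "crest_best.xyz")
    if (!file.exists(best))
      stop(structure(class = c("EngineUnavailable", "error", "condition"),
                     list(message = "CREST produced no conformer",
                          call = sys.call(-1))))
    read_xyz_text(paste(readLines(best), collapse = "\n"), "conformer")
  }
}
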