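#' Energy matrix
#'
#' Additive sequence model of a Gibbs free energy contribution (kcal/mol):
#' \eqn{\Delta G(x) = G_0 + \sum_l M_{l, x_l}} over a footprint — a
#' contiguous sub-window of the assayed region. Energy matrices are the
#' biophysical guise of additive G-P map components.
#'
#' @slot mat footprint-length x C matrix of per-(position, character)
#'   energies.
#' @slot offset scalar reference energy \eqn{G_0}.
#' @slot start 0-based start of the footprint within the assayed region.
#' @slot name label used for parameter names.
#' @export
setClass("EnergyMatrix",
  representation(mat = "matrix", offset = "numeric", start = "integer",
                 name = "character"))

#' @rdname EnergyMatrix-class
#' @param mat footprint-length x C energy matrix.
#' @param offset scalar reference energy.
#' @param start 0-based footprint start.
#' @param name component label.
#' @export
energyMatrix <- function(mat, offset = 0, start = 0L, name = "G") {
  new("EnergyMatrix", mat = as.matrix(mat), offset = as.numeric(offset),
      start = as.integer(start), name = name)
}

# per-sequence energies of one matrix given the index matrix of the
# assayed region
.em_energy <- function(em, idx) {
  fl <- nrow(em@mat)
  if (em@start + fl > ncol(idx))
    stop("energy matrix footprint [", em@start, ", ", em@start + fl,
         ") lies outside the assayed region (L = ", ncol(idx), ")")
  e <- rep(em@offset, nrow(idx))
  for (l in seq_len(fl)) e <- e + em@mat[l, idx[, em@start + l]]
  e
}

#' Thermodynamic G-P map
#'
#' A quasi-equilibrium model: the molecular system occupies one of a few
#' states, each with a Gibbs free energy that is a sum of energy-matrix
#' outputs and scalar interaction energies; the latent phenotype is the
#' Boltzmann occupancy of a readout subset of states,
#' \deqn{\phi(x) = \frac{\sum_{s \in readout} e^{-\beta G_s(x)}}
#'                     {\sum_{s} e^{-\beta G_s(x)}}.}
#' One state (typically the first) has all-zero energy and serves as the
#' reference. The inverse temperature defaults to
#' \eqn{\beta = 1/0.593\,\mathrm{mol/kcal}} (about 300 K). Occupancies sum
#' to 1 and are invariant under adding a constant to all state energies;
#' a log-sum-exp shift guards overflow.
#'
#' @slot matrices named list of \linkS4class{EnergyMatrix} components.
#' @slot scalars named numeric vector of scalar interaction energies.
#' @slot states named list; each element is a character vector naming the
#'   matrix/scalar components summed into that state's energy (empty =
#'   reference state at 0).
#' @slot readout names of the states whose total occupancy is \eqn{\phi}.
#' @slot beta inverse temperature in 1/(kcal/mol).
#' @export
setClass("ThermodynamicModel",
  representation(matrices = "list", scalars = "numeric", states = "list",
                 readout = "character", beta = "numeric"))

setValidity("ThermodynamicModel", function(object) {
  if (!length(object@readout)) return("readout must be nonempty")
  if (!all(object@readout %in% names(object@states)))
    return("readout must name states")
  comps <- c(names(object@matrices), names(object@scalars))
  for (st in object@states)
    if (length(st) && !all(st %in% comps))
      return("state components must name matrices or scalars")
  if (!any(vapply(object@states, length, 0L) == 0L))
    return("need a reference state with zero energy")
  TRUE
})

#' @rdname ThermodynamicModel-class
#' @param matrices,scalars,states,readout,beta see the class slots.
#' @export
thermodynamicModel <- function(matrices, scalars = numeric(0), states,
                               readout, beta = 1 / 0.593) {
  new("ThermodynamicModel", matrices = matrices, scalars = scalars,
      states = states, readout = readout, beta = beta)
}

# per-sequence state energy matrix [n x nStates]
.thermo_energies <- function(model, idx) {
  matE <- lapply(model@matrices, .em_energy, idx = idx)
  n <- nrow(idx)
  E <- matrix(0, n, length(model@states),
              dimnames = list(NULL, names(model@states)))
  for (s in names(model@states)) for (comp in model@states[[s]]) {
    E[, s] <- E[, s] + if (comp %in% names(model@matrices)) matE[[comp]]
                       else model@scalars[[comp]]
  }
  E
}

#' Boltzmann occupancy of the readout states
#'
#' @param model a \linkS4class{ThermodynamicModel}.
#' @param sequences sequences spanning the assayed region.
#' @param alphabet the alphabet the energy matrices are defined over.
#' @return The latent phenotype \eqn{\phi \in (0, 1)} per sequence.
#' @export
boltzmannOccupancy <- function(model, sequences, alphabet) {
  idx <- .seq_to_idx(sequences, alphabet)
  E <- .thermo_energies(model, idx)
  W <- -model@beta * E
  mx <- apply(W, 1, max)
  w <- exp(W - mx)
  rowSums(w[, model@readout, drop = FALSE]) / rowSums(w)
}

#' Three-state folding/binding G-P map (GB1-style)
#'
#' States: unfolded (reference, energy 0), folded-unbound
#' (\eqn{\Delta G_F(x)}), and folded-bound
#' (\eqn{\Delta G_F(x) + \Delta G_B(x)}); both energies come from energy
#' matrices over the protein alphabet, and ligand concentration is
#' absorbed into the binding offset. The latent phenotype is the
#' fraction of time the protein is in the folded-bound state.
#'
#' @param foldMat,bindMat L x C energy matrices (kcal/mol).
#' @param foldOffset,bindOffset scalar reference energies.
#' @param alphabet alphabet (default protein).
#' @param beta inverse temperature.
#' @return A \linkS4class{ThermodynamicModel}.
#' @export
gb1ThreeState <- function(foldMat, bindMat, foldOffset = 0, bindOffset = 0,
                          alphabet = builtinAlphabet("protein"),
                          beta = 1 / 0.593) {
  thermodynamicModel(
    matrices = list(GF = energyMatrix(foldMat, foldOffset, 0L, "GF"),
                    GB = energyMatrix(bindMat, bindOffset, 0L, "GB")),
    states = list(unfolded = character(0), folded = "GF",
                  bound = c("GF", "GB")),
    readout = "bound", beta = beta)
}

#' Four-state transcriptional activation G-P map (lac-promoter-style)
#'
#' States: empty promoter (reference), CRP-bound (\eqn{\Delta G_C(x)}),
#' RNAP-bound (\eqn{\Delta G_R(x)}), and doubly bound
#' (\eqn{\Delta G_C + \Delta G_R + \Delta G_I}); the binding energies come
#' from energy matrices over the DNA footprints of the two proteins, and
#' the CRP-RNAP interaction \eqn{\Delta G_I} is a scalar. The latent
#' phenotype is the fraction of time the promoter is RNAP-bound (singly
#' or doubly).
#'
#' @param crpMat,rnapMat footprint x C energy matrices.
#' @param dGI scalar CRP-RNAP interaction energy (kcal/mol).
#' @param crpStart,rnapStart 0-based footprint starts in the assayed
#'   region.
#' @param crpOffset,rnapOffset scalar binding offsets (chemical
#'   potentials absorbed).
#' @param beta inverse temperature.
#' @return A \linkS4class{ThermodynamicModel}.
#' @export
lacFourState <- function(crpMat, rnapMat, dGI, crpStart = 0L,
                         rnapStart = 0L, crpOffset = 0, rnapOffset = 0,
                         beta = 1 / 0.593) {
  thermodynamicModel(
    matrices = list(
      GC = energyMatrix(crpMat, crpOffset, crpStart, "GC"),
      GR = energyMatrix(rnapMat, rnapOffset, rnapStart, "GR")),
    scalars = c(GI = dGI),
    states = list(empty = character(0), crp = "GC", rnap = "GR",
                  both = c("GC", "GR", "GI")),
    readout = c("rnap", "both"), beta = beta)
}

#' Wrap a thermodynamic model as a trainable custom G-P map
#'
#' Exposes all energy-matrix entries, offsets and scalar interaction
#' energies as a flat parameter vector, with an analytic gradient of the
#' Boltzmann occupancy, so the model can be trained through either
#' measurement process, simulated from, and bootstrapped. Like all custom
#' maps it is not gauge-fixed automatically (energy matrices have their
#' own gauge freedoms; \code{\link{hierarchicalGauge}} can be applied to
#' individual matrices for display).
#'
#' @param model a \linkS4class{ThermodynamicModel}.
#' @param L length of the assayed region.
#' @param alphabet sequence alphabet.
#' @return A \linkS4class{CustomGPMap} whose parameters are named
#'   \code{<mat>.offset}, \code{<mat>.l.c}, and scalar names.
#' @export
thermodynamicGPMap <- function(model, L, alphabet) {
  C <- alphabetSize(alphabet)
  # parameter layout
  pn <- character(0)
  for (nm in names(model@matrices)) {
    em <- model@matrices[[nm]]
    pn <- c(pn, paste0(nm, ".offset"),
            paste0(nm, ".", rep(seq_len(nrow(em@mat)) - 1L, each = C),
                   ".", rep(alphabet@characters, nrow(em@mat))))
  }
  pn <- c(pn, names(model@scalars))
  p0 <- numeric(0)
  for (nm in names(model@matrices)) {
    em <- model@matrices[[nm]]
    p0 <- c(p0, em@offset, as.vector(t(em@mat)))
  }
  p0 <- c(p0, unname(model@scalars))
  names(p0) <- pn

  rebuild <- function(params) {
    off <- 0L
    mdl <- model
    for (nm in names(mdl@matrices)) {
      em <- mdl@matrices[[nm]]
      fl <- nrow(em@mat)
      em@offset <- params[[off + 1L]]
      em@mat <- matrix(params[(off + 2L):(off + 1L + fl * C)], fl, C,
                       byrow = TRUE)
      mdl@matrices[[nm]] <- em
      off <- off + 1L + fl * C
    }
    if (length(mdl@scalars))
      mdl@scalars[] <- params[(off + 1L):(off + length(mdl@scalars))]
    mdl
  }

  phiFun <- function(params, idx) {
    mdl <- rebuild(params)
    E <- .thermo_energies(mdl, idx)
    W <- -mdl@beta * E
    mx <- apply(W, 1, max)
    w <- exp(W - mx)
    rowSums(w[, mdl@readout, drop = FALSE]) / rowSums(w)
  }

  gradFun <- function(params, idx, dphi) {
    mdl <- rebuild(params)
    E <- .thermo_energies(mdl, idx)
    W <- -mdl@beta * E
    mx <- apply(W, 1, max)
    w <- exp(W - mx)
    tot <- rowSums(w)
    p <- w / tot
    phiV <- rowSums(p[, mdl@readout, drop = FALSE])
    inR <- names(mdl@states) %in% mdl@readout
    # dphi/dG_s = -beta * p_s * (1[s in readout] - phi)
    dG <- -mdl@beta * p *
      (matrix(inR, nrow(p), ncol(p), byrow = TRUE) - phiV)
    # accumulate per component: sum over states containing it
    compW <- list()
    for (comp in c(names(mdl@matrices), names(mdl@scalars))) {
      v <- numeric(nrow(idx))
      for (s in names(mdl@states))
        if (comp %in% mdl@states[[s]]) v <- v + dG[, s]
      compW[[comp]] <- v * dphi
    }
    g <- numeric(length(params))
    off <- 0L
    for (nm in names(mdl@matrices)) {
      em <- mdl@matrices[[nm]]
      fl <- nrow(em@mat)
      cw <- compW[[nm]]
      g[off + 1L] <- sum(cw)
      gm <- matrix(0, fl, C)
      for (l in seq_len(fl)) {
        ci <- idx[, em@start + l]
        gm[l, ] <- vapply(seq_len(C), function(cc) sum(cw[ci == cc]), 0)
      }
      g[(off + 2L):(off + 1L + fl * C)] <- as.vector(t(gm))
      off <- off + 1L + fl * C
    }
    for (j in seq_along(mdl@scalars))
      g[off + j] <- sum(compW[[names(mdl@scalars)[j]]])
    g
  }

  customGPMap(L, alphabet, phiFun = phiFun, params = p0,
              gradFun = gradFun,
              prepare = function(sequences, alphabet)
                .seq_to_idx(sequences, alphabet))
}
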