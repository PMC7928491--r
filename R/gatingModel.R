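## Rates live in s^-1 inside model objects and model files; dwell times
## are reported in ms everywhere downstream. Conversion happens here only.
.S_TO_MS <- 1000

#' Construct a gating model
#'
#' Build a [GatingModel] from its parts. The generator `Q` is given in
#' s^-1 with off-diagonal entries the transition rates; the diagonal is
#' recomputed as minus the row sum, so it may be supplied as zero.
#'
#' @param stateNames character vector of unique state identifiers.
#' @param conductanceClass per-state class label; `"closed"` plus one or
#'   more open classes (e.g. `"open_small"`, `"open_large"`).
#' @param classAmplitude named numeric map class -> unitary current
#'   magnitude in pA (`closed` must map to 0).
#' @param Q square numeric rate matrix in s^-1.
#' @param initialDistribution optional probability vector over states;
#'   when omitted the equilibrium distribution is used where needed.
#' @return a validated [GatingModel].
#' @examples
#' m <- gatingModel(
#'   stateNames = c("C", "O"),
#'   conductanceClass = c("closed", "open_small"),
#'   classAmplitude = c(closed = 0, open_small = 1.35),
#'   Q = matrix(c(0, 100, 500, 0), 2, 2, byrow = TRUE)
#' )
#' equilibriumDistribution(m)
#' @export
gatingModel <- function(stateNames, conductanceClass, classAmplitude, Q,
                        initialDistribution = numeric(0)) {
  Q <- as.matrix(Q)
  dimnames(Q) <- list(stateNames, stateNames)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  new("GatingModel",
      stateNames = as.character(stateNames),
      conductanceClass = as.character(conductanceClass),
      classAmplitude = unlist(classAmplitude),
      Q = Q,
      initialDistribution = as.numeric(initialDistribution))
}

#' Validate a gating model without raising
#'
#' Returns every invariant violation found in the model as a character
#' vector of human-readable descriptions; a well-formed model yields
#' `character(0)`. Unlike `validObject`, this never throws.
#'
#' @param model a [GatingModel] (possibly malformed).
#' @return character vector of violations (empty if valid).
#' @export
validateModel <- function(model) {
  .validateGatingModel(model)
}

.stopIfInvalid <- function(model) {
  bad <- .validateGatingModel(model)
  if (length(bad))
    stop("invalid gating model: ", paste(bad, collapse = "; "))
  invisible(model)
}

.openStates <- function(model) which(model@conductanceClass != .CLOSED_CLASS)
.closedStates <- function(model) which(model@conductanceClass == .CLOSED_CLASS)

#' Per-state current level in pA
#'
#' @param model a [GatingModel].
#' @return numeric vector of unitary current magnitudes, one per state.
#' @export
stateAmplitudes <- function(model) {
  unname(model@classAmplitude[model@conductanceClass])
}

#' Equilibrium state distribution of a gating model
#'
#' Solves pi Q = 0 with sum(pi) = 1 by a direct linear solve. The chain
#' must be irreducible (all states mutually reachable).
#'
#' @param model a valid [GatingModel].
#' @return named probability vector over states with residual
#'   `max |pi Q| < 1e-10`.
#' @export
equilibriumDistribution <- function(model) {
  .stopIfInvalid(model)
  Q <- model@Q
  n <- nrow(Q)
  if (!.isIrreducible(Q))
    stop("rate matrix is reducible: some states are disconnected")
  ## replace one balance equation by the normalization constraint
  A <- rbind(t(Q)[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1), 1)
  pi_hat <- solve(A, b)
  pi_hat[abs(pi_hat) < 1e-15] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  res <- max(abs(pi_hat %*% Q))
  if (res >= 1e-10)
    stop(sprintf("equilibrium solve residual %g exceeds 1e-10", res))
  stats::setNames(as.numeric(pi_hat), model@stateNames)
}

.isIrreducible <- function(Q) {
  ## strong connectivity on the directed graph of positive rates
  n <- nrow(Q)
  adj <- Q > 0
  reach <- function(A) {
    r <- rep(FALSE, n); r[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !r)
      r[nxt] <- TRUE; frontier <- nxt
    }
    all(r)
  }
  reach(adj) && reach(t(adj))
}

#' Theoretical dwell-time mixture of an aggregate
#'
#' Computes the exponential-mixture structure of sojourn times in the
#' open or closed aggregate of a gating model by spectral expansion of
#' the sub-generator restricted to the aggregate. With `Q_AA` the block
#' of `Q` over aggregate states, the sojourn density is
#' `f(t) = phi exp(Q_AA t) (-Q_AA) 1`, where `phi` is the equilibrium
#' entry distribution into the aggregate. Eigen-decomposition of `Q_AA`
#' turns this into a sum of exponentials whose time constants are
#' `-1/eigenvalue` (converted to ms) and whose areas are the
#' entry-weighted spectral weights, normalized to sum to 1.
#'
#' No missed-event correction is applied at this layer; finite
#' resolution is handled at idealization (dead time) and fitting
#' (left truncation).
#'
#' @param model a valid, irreducible [GatingModel].
#' @param classGroup `"closed"` for the closed aggregate or `"open"`
#'   for the open aggregate (all open classes pooled).
#' @return data.frame with columns `tau_ms` (ascending) and `area`.
#' @export
predictedDwellComponents <- function(model,
                                     classGroup = c("closed", "open")) {
  .stopIfInvalid(model)
  classGroup <- match.arg(classGroup)
  if (!.isIrreducible(model@Q))
    stop("rate matrix is reducible: some states are disconnected")
  inA <- if (classGroup == "closed") .closedStates(model) else .openStates(model)
  outA <- setdiff(seq_along(model@stateNames), inA)
  Q <- model@Q
  Qaa <- Q[inA, inA, drop = FALSE]
  pi_eq <- equilibriumDistribution(model)
  ## equilibrium entry distribution: rate of entering A at state j
  phi <- as.numeric(pi_eq[outA] %*% Q[outA, inA, drop = FALSE])
  if (sum(phi) <= 0) stop("aggregate is never entered at equilibrium")
  phi <- phi / sum(phi)
  eg <- eigen(Qaa)
  if (max(abs(Im(eg$values))) > 1e-8 * max(abs(eg$values)))
    stop("sub-generator has complex eigenvalues; perturb rates slightly")
  lam <- Re(eg$values)
  if (any(lam >= 0)) stop("sub-generator eigenvalues must be negative")
  if (length(lam) > 1 &&
      min(abs(diff(sort(lam)))) < 1e-9 * max(abs(lam)))
    stop("degenerate (repeated) eigenvalues in sub-generator; perturb rates slightly")
  V <- Re(eg$vectors)
  W <- solve(V)
  exit <- -as.numeric(Qaa %*% rep(1, nrow(Qaa)))
  ## f(t) = sum_k c_k exp(lam_k t); area_k = c_k * tau_k
  ck <- vapply(seq_along(lam), function(k) {
    as.numeric((phi %*% V[, k]) * (W[k, ] %*% exit))
  }, numeric(1))
  tau_s <- -1 / lam
  area <- ck * tau_s
  area <- area / sum(area)
  ord <- order(tau_s)
  data.frame(tau_ms = tau_s[ord] * .S_TO_MS, area = area[ord])
}

#' Build a gating model with a prescribed dwell-time mixture
#'
#' Constructs a generic scheme whose closed- and open-aggregate
#' dwell-time mixtures are exactly the requested exponential mixtures.
#' The scheme is complete-bipartite: closed states do not interconnect
#' (so each closed state contributes one pure exponential with
#' `tau = 1/exit rate`), and the entry probability into each closed
#' state equals its requested area regardless of which open state the
#' channel closes from (and symmetrically for open states). All open
#' states share a single conductance class/amplitude.
#'
#' @param closedTau,closedArea closed-mixture time constants (ms) and
#'   fractional areas (areas are normalized to sum to 1).
#' @param openTau,openArea open-mixture time constants (ms) and areas.
#' @param openAmplitude unitary open-current magnitude in pA.
#' @param openClass label of the open conductance class.
#' @return a [GatingModel].
#' @examples
#' ## closed mixture ~ 0.8 ms (30%) + 250 ms (70%); open ~ 1.5 ms
#' m <- mixtureGatingModel(c(0.8, 250), c(0.3, 0.7), 1.5, 1)
#' predictedDwellComponents(m, "closed")
#' @export
mixtureGatingModel <- function(closedTau, closedArea, openTau, openArea,
                               openAmplitude = 1.35,
                               openClass = "open_small") {
  stopifnot(length(closedTau) == length(closedArea),
            length(openTau) == length(openArea),
            all(closedTau > 0), all(openTau > 0),
            all(closedArea > 0), all(openArea > 0))
  closedArea <- closedArea / sum(closedArea)
  openArea <- openArea / sum(openArea)
  nc <- length(closedTau); no <- length(openTau)
  states <- c(paste0("C", seq_len(nc)), paste0("O", seq_len(no)))
  cls <- c(rep(.CLOSED_CLASS, nc), rep(openClass, no))
  n <- nc + no
  Q <- matrix(0, n, n)
  for (i in seq_len(nc)) {
    exit <- .S_TO_MS / closedTau[i]
    Q[i, nc + seq_len(no)] <- exit * openArea
  }
  for (j in seq_len(no)) {
    exit <- .S_TO_MS / openTau[j]
    Q[nc + j, seq_len(nc)] <- exit * closedArea
  }
  amp <- c(0, openAmplitude)
  names(amp) <- c(.CLOSED_CLASS, openClass)
  gatingModel(states, cls, amp, Q)
}

#' Build a two-amplitude-class gating model with class-segregated bursts
#'
#' Constructs a scheme emulating the low-sensitivity (LS) receptor
#' isoform, whose openings fall into a small (`O_S`) and a large
#' (`O_L`) unitary-amplitude class and whose bursts contain openings of
#' a single class only. Each class has one open state and a private
#' within-burst closed state (the shortest closed component); the
#' remaining, longer closed components are shared states from which the
#' next burst's class is drawn with probability `classWeight`.
#'
#' @param closedTau,closedArea closed-mixture time constants (ms) and
#'   areas; component 1 is the within-burst closure and is split
#'   between the two classes.
#' @param openTauS,openTauL mean open time (ms) of the small/large class.
#' @param amplitudeS,amplitudeL unitary amplitudes in pA.
#' @param classWeight probability that activity after a long closure is
#'   of the small class.
#' @return a [GatingModel] with classes `open_small` and `open_large`.
#' @export
twoClassBurstModel <- function(closedTau, closedArea,
                               openTauS = 0.7, openTauL = 1.5,
                               amplitudeS = 1.05, amplitudeL = 2.06,
                               classWeight = 0.6) {
  stopifnot(length(closedTau) >= 2, length(closedTau) == length(closedArea),
            all(closedTau > 0), all(closedArea > 0),
            classWeight > 0, classWeight < 1)
  closedArea <- closedArea / sum(closedArea)
  nl <- length(closedTau) - 1L           # number of shared long closed states
  states <- c("CbS", "CbL", paste0("C", seq_len(nl) + 1L), "OS", "OL")
  cls <- c(.CLOSED_CLASS, .CLOSED_CLASS, rep(.CLOSED_CLASS, nl),
           "open_small", "open_large")
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  iOS <- n - 1L; iOL <- n
  ## within-burst closed states reopen into their own class only; the
  ## large-class rate is nudged by 2% so the closed sub-generator has
  ## no repeated eigenvalue (degenerate spectra are rejected upstream)
  Q["CbS", iOS] <- .S_TO_MS / closedTau[1]
  Q["CbL", iOL] <- 1.02 * .S_TO_MS / closedTau[1]
  ## shared long closures re-open into either class
  for (j in seq_len(nl)) {
    exit <- .S_TO_MS / closedTau[j + 1L]
    Q[2L + j, iOS] <- exit * classWeight
    Q[2L + j, iOL] <- exit * (1 - classWeight)
  }
  ## open-state exits: fraction a1 back to the class's burst closure,
  ## remainder to the shared closures in proportion to their areas
  longArea <- closedArea[-1] / sum(closedArea[-1])
  for (cl in c("S", "L")) {
    io <- if (cl == "S") iOS else iOL
    exit <- .S_TO_MS / (if (cl == "S") openTauS else openTauL)
    Q[io, paste0("Cb", cl)] <- exit * closedArea[1]
    Q[io, 2L + seq_len(nl)] <- exit * (1 - closedArea[1]) * longArea
  }
  amp <- c(0, amplitudeS, amplitudeL)
  names(amp) <- c(.CLOSED_CLASS, "open_small", "open_large")
  gatingModel(states, cls, amp, Q)
}

#' Read / write gating models as JSON
#'
#' The on-disk schema has keys `states` (character), `classes`
#' (per-state conductance class), `amplitudes_pA` (named map class ->
#' pA), `Q_per_s` (row-major rate matrix in s^-1) and optional
#' `initial` (probability vector). The file is validated on load.
#'
#' @param path file path.
#' @return `readGatingModel`: a validated [GatingModel].
#' @examples
#' ## synthetic example model shipped with the package
#' readGatingModel(system.file("extdata", "hs_like_synthetic_model.json",
#'                             package = "sckinetics"))
#' @export
readGatingModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("states", "classes", "amplitudes_pA", "Q_per_s"))
    if (is.null(j[[key]]))
      stop("model file missing required key '", key, "'")
  ns <- length(j$states)
  Q <- matrix(as.numeric(unlist(j$Q_per_s)), nrow = ns, byrow = TRUE)
  m <- gatingModel(j$states, j$classes, unlist(j$amplitudes_pA), Q,
                   initialDistribution =
                     if (is.null(j$initial)) numeric(0) else as.numeric(j$initial))
  bad <- validateModel(m)
  if (length(bad))
    stop("invalid model in ", path, ": ", paste(bad, collapse = "; "))
  m
}

#' @rdname readGatingModel
#' @param model a [GatingModel] to serialize.
#' @export
writeGatingModel <- function(model, path) {
  .stopIfInvalid(model)
  obj <- list(
    states = model@stateNames,
    classes = model@conductanceClass,
    amplitudes_pA = as.list(model@classAmplitude),
    Q_per_s = apply(model@Q, 1, function(r) as.numeric(r), simplify = FALSE)
  )
  if (length(model@initialDistribution))
    obj$initial <- model@initialDistribution
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
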