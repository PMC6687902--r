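#' @importFrom rlang .data
NULL

# Four neuronal populations per cortical source, in fixed order.
# ss = spiny stellate (granular), sp = superficial pyramidal,
# ii = inhibitory interneuron, dp = deep pyramidal.
cmc_populations <- function() c("ss", "sp", "ii", "dp")

# Prior-mean synaptic rate constants (s^-1) per population. Excitatory
# granular/supragranular populations are fast (2 ms time constants);
# interneurons and deep pyramidal cells are slower, which places the
# linearized impulse-response peak of the coupled circuit near 100 ms.
cmc_kappa0 <- function() {
  c(ss = 1 / 0.002, sp = 1 / 0.002, ii = 1 / 0.016, dp = 1 / 0.028)
}

# Intrinsic (within-source) coupling template, target rows x source
# columns over (ss, sp, ii, dp). Signed dimensionless weights:
#  - every population has recurrent self-inhibition (-8),
#  - spiny stellate cells excite both pyramidal populations and the
#    interneurons (+4 / +2),
#  - interneurons inhibit superficial and deep pyramidal cells (-4).
# There is no intrinsic positive feedback loop, which keeps the
# unforced circuit damped for any positive gain scaling.
cmc_intrinsic_template <- function() {
  G <- matrix(0, 4, 4, dimnames = list(cmc_populations(), cmc_populations()))
  G["ss", "ss"] <- -8
  G["sp", "ss"] <- 4
  G["ii", "ss"] <- 4
  G["dp", "ss"] <- 2
  G["sp", "sp"] <- -8
  G["ii", "ii"] <- -8
  G["dp", "dp"] <- -8
  G["sp", "ii"] <- -4
  G["dp", "ii"] <- -4
  G
}

# Intrinsic gain classes: one log-scaling per class of connection.
cmc_intrinsic_classes <- function() {
  G <- cmc_intrinsic_template()
  cls <- matrix(NA_character_, 4, 4,
    dimnames = list(cmc_populations(), cmc_populations())
  )
  cls[G < 0 & row(G) == col(G)] <- "self"
  cls[G > 0] <- "exc"
  cls[G < 0 & row(G) != col(G)] <- "inh"
  cls
}

# Extrinsic (between-source) component templates. Ascending connections
# arise from superficial pyramidal cells and excite spiny stellate (A1)
# and deep pyramidal (A2) populations of the higher source; descending
# connections arise from deep pyramidal cells and inhibit superficial
# pyramidal (A3) and interneuron (A4) populations of the lower source.
# `weight` is a positive magnitude; `sign` carries the excitatory or
# inhibitory wiring convention. Backward connections are slightly
# weaker at baseline than forward ones.
cmc_extrinsic_template <- local({
  tmpl <- NULL
  function() {
    if (is.null(tmpl)) {
      tmpl <<- tibble::tribble(
        ~type,      ~component, ~from_pop, ~to_pop, ~weight, ~sign,
        "forward",  "A1",       "sp",      "ss",    8,       1,
        "forward",  "A2",       "sp",      "dp",    4,       1,
        "backward", "A3",       "dp",      "sp",    4,      -1,
        "backward", "A4",       "dp",      "ii",    2,      -1
      )
    }
    tmpl
  }
})

#' Construct the five-source attention-network model
#'
#' Builds the network used throughout the package: a bilateral dorsal
#' attention network (left/right frontal eye fields and intraparietal
#' sulci) coupled to the right temporoparietal junction, which
#' represents the (right-lateralized) ventral attention network.
#' Ascending connections run from rTPJ to both FEFs and from each IPS
#' to its ipsilateral FEF; each ascending connection has a matching
#' descending counterpart. Exogenous (geniculate) input drives the
#' sources lowest in the visual hierarchy: rTPJ and both IPS sources.
#'
#' The four connections linking the ventral and dorsal networks may
#' change their gain with experimental condition; they are numbered
#' 1 = rTPJ to left FEF, 2 = rTPJ to right FEF, 3 = left FEF to rTPJ,
#' 4 = right FEF to rTPJ.
#'
#' @param design a tibble with columns `condition` (labels) and
#'   `covariate` (one scalar per condition per modulatory effect).
#'   Defaults to the two-condition early/late contrast with covariate
#'   values 0 and 1.
#'
#' @return An object of class `cmc_network` with elements `sources`,
#'   `edges` (a tibble of directed typed edges with modulation
#'   numbering), `input_targets`, and `design`.
#' @export
#'
#' @examples
#' net <- build_attention_network()
#' net$edges
build_attention_network <- function(design = NULL) {
  sources <- c("lFEF", "rFEF", "lIPS", "rIPS", "rTPJ")
  edges <- tibble::tribble(
    ~from,   ~to,     ~type,      ~effect,
    "rTPJ",  "lFEF",  "forward",  1L,
    "rTPJ",  "rFEF",  "forward",  2L,
    "lIPS",  "lFEF",  "forward",  NA_integer_,
    "rIPS",  "rFEF",  "forward",  NA_integer_,
    "lFEF",  "rTPJ",  "backward", 3L,
    "rFEF",  "rTPJ",  "backward", 4L,
    "lFEF",  "lIPS",  "backward", NA_integer_,
    "rFEF",  "rIPS",  "backward", NA_integer_
  )
  edges$label <- paste0(edges$from, "->", edges$to)
  edges$masked <- !is.na(edges$effect)
  if (is.null(design)) {
    design <- tibble::tibble(
      condition = c("early", "late"),
      covariate = c(0, 1)
    )
  }
  net <- structure(
    list(
      sources = sources,
      edges = edges,
      input_targets = c("rTPJ", "lIPS", "rIPS"),
      design = tibble::as_tibble(design)
    ),
    class = "cmc_network"
  )
  validate_network(net)
  net
}

#' Validate a network specification
#'
#' Checks the structural invariants of a `cmc_network`: forward and
#' backward edge sets are disjoint as directed pairs, modulated edges
#' are a subset of the declared edges, and input targets are declared
#' sources.
#'
#' @param net a `cmc_network`.
#' @return `net`, invisibly, or an error describing the violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "cmc_network"))
  e <- net$edges
  fwd <- e$label[e$type == "forward"]
  bwd <- e$label[e$type == "backward"]
  if (length(intersect(fwd, bwd)) > 0) {
    stop("forward and backward edge sets must be disjoint as directed pairs",
      call. = FALSE
    )
  }
  if (anyDuplicated(e$label)) {
    stop("duplicate edges in network", call. = FALSE)
  }
  if (!all(c(e$from, e$to) %in% net$sources)) {
    stop("edge endpoints must be declared sources", call. = FALSE)
  }
  if (!all(net$input_targets %in% net$sources)) {
    stop("input targets must be declared sources", call. = FALSE)
  }
  eff <- e$effect[!is.na(e$effect)]
  if (anyDuplicated(eff)) stop("modulation numbering must be unique", call. = FALSE)
  if (!all(c("condition", "covariate") %in% names(net$design))) {
    stop("design must have `condition` and `covariate` columns", call. = FALSE)
  }
  invisible(net)
}

#' @export
print.cmc_network <- function(x, ...) {
  cat(
    "<cmc_network>", length(x$sources), "sources,",
    nrow(x$edges), "extrinsic edges (", sum(x$edges$masked),
    "modulated ),", nrow(x$design), "conditions\n"
  )
  print(x$edges)
  invisible(x)
}

# number of state dimensions: 4 populations x (voltage, conductance)
n_states <- function(net) 8L * length(net$sources)

#' Condition-specific effective connection gains
#'
#' Computes the positive gain of every extrinsic connection component
#' under a given experimental condition. Log-scaling parameters enter
#' through the exponential, so an excitatory connection can never
#' become inhibitory (and vice versa): for an unmodulated edge the
#' gain is `template * exp(a)`, and for a modulated edge
#' `template * exp(a + b * X)` where `X` is the condition's covariate.
#'
#' @param params a `cmc_params` object.
#' @param net a `cmc_network`.
#' @param condition_index integer row of `net$design`.
#'
#' @return A tibble with one row per edge component (two components per
#'   edge), columns `label`, `from`, `to`, `type`, `component`,
#'   `template`, `gain` (positive magnitude) and `sign`.
#' @export
effective_gains <- function(params, net, condition_index = 1L) {
  stopifnot(inherits(net, "cmc_network"))
  if (!(condition_index %in% seq_len(nrow(net$design)))) {
    stop(
      "unknown condition index ", condition_index, " (design has ",
      nrow(net$design), " conditions)",
      call. = FALSE
    )
  }
  X <- net$design$covariate[condition_index]
  tmpl <- cmc_extrinsic_template()
  e <- net$edges
  a <- ifelse(e$type == "forward",
    params$a_fwd[e$label],
    params$a_bwd[e$label]
  )
  b_eff <- rep(0, nrow(e))
  b_eff[e$masked] <- params$b[paste0("b", e$effect[e$masked])]
  scale <- exp(a + b_eff * X)
  out <- dplyr::inner_join(
    tibble::tibble(
      label = e$label, from = e$from, to = e$to,
      type = e$type, scale = scale
    ),
    tmpl,
    by = "type",
    relationship = "many-to-many"
  )
  out$gain <- out$weight * out$scale
  dplyr::select(
    out, "label", "from", "to", "type", "component",
    "from_pop", "to_pop", template = "weight", "gain", "sign"
  )
}

#' Presynaptic firing-rate transform
#'
#' Maps population voltage to a (dimensionless) presynaptic firing
#' rate. The transform is a centered sigmoid, `tanh(gain * v)`:
#' monotone, bounded, odd-symmetric, with `firing_rate(0) = 0` so the
#' zero state is an exact fixed point of the unforced circuit, and
#' slope `gain` at the origin.
#'
#' @param v voltage (mV); vectorized.
#' @param gain slope at zero (default 1).
#' @return firing rate values in (-1, 1).
#' @export
firing_rate <- function(v, gain = 1) tanh(gain * v)

# Assemble the condition-specific coupling operator.
# Returns W (4n x 4n; drive = W f(v)), cvec (input weights into spiny
# stellate rows), and kappa (length 4n rate constants, s^-1).
build_coupling <- function(params, net, condition_index = 1L) {
  pops <- cmc_populations()
  ns <- length(net$sources)
  np <- 4L * ns
  idx <- function(src, pop) {
    (match(src, net$sources) - 1L) * 4L + match(pop, pops)
  }
  # intrinsic blocks with per-class gain scaling
  G0 <- cmc_intrinsic_template()
  cls <- cmc_intrinsic_classes()
  g_scale <- matrix(1, 4, 4)
  g_scale[!is.na(cls)] <- exp(unname(params$g[cls[!is.na(cls)]]))
  G <- G0 * g_scale
  W <- matrix(0, np, np)
  for (s in seq_len(ns)) {
    r <- (s - 1L) * 4L + 1:4
    W[r, r] <- G
  }
  # extrinsic components at condition-specific gains (numeric fast
  # path equivalent to effective_gains(); kept in sync by tests)
  e <- net$edges
  if (!(condition_index %in% seq_len(nrow(net$design)))) {
    stop(
      "unknown condition index ", condition_index, " (design has ",
      nrow(net$design), " conditions)",
      call. = FALSE
    )
  }
  X <- net$design$covariate[condition_index]
  a <- ifelse(e$type == "forward",
    params$a_fwd[e$label], params$a_bwd[e$label]
  )
  b_eff <- rep(0, nrow(e))
  b_eff[e$masked] <- params$b[paste0("b", e$effect[e$masked])]
  scale <- exp(a + b_eff * X)
  tmpl <- cmc_extrinsic_template()
  for (i in seq_len(nrow(e))) {
    comps <- tmpl[tmpl$type == e$type[i], ]
    for (j in seq_len(nrow(comps))) {
      r <- idx(e$to[i], comps$to_pop[j])
      cc <- idx(e$from[i], comps$from_pop[j])
      W[r, cc] <- W[r, cc] + comps$sign[j] * comps$weight[j] * scale[i]
    }
  }
  # exogenous drive into spiny stellate cells of input targets
  cvec <- numeric(np)
  for (tg in net$input_targets) {
    cvec[idx(tg, "ss")] <- exp(unname(params$c[tg]))
  }
  # rates ordered (src1: ss..dp, src2: ss..dp, ...)
  kappa <- rep(cmc_kappa0() * exp(unname(params$kappa)), ns)
  list(W = W, cvec = cvec, kappa = kappa, n_sources = ns)
}

# Internal flow on precomputed coupling. x interleaves (voltage,
# conductance) pairs per population; u is a scalar drive value.
cmc_flow_raw <- function(x, u, coup, firing_gain = 1) {
  np <- length(coup$kappa)
  vi <- seq(1L, 2L * np, by = 2L)
  v <- x[vi]
  g <- x[vi + 1L]
  drive <- as.vector(coup$W %*% firing_rate(v, firing_gain)) + coup$cvec * u
  k <- coup$kappa
  dx <- numeric(2L * np)
  dx[vi] <- g
  dx[vi + 1L] <- k * drive - 2 * k * g - k * k * v
  dx
}

#' Deterministic flow of the canonical-microcircuit network
#'
#' Evaluates the time derivative of the full state vector. Each
#' population obeys a damped second-order synaptic convolution:
#' voltage' = conductance and
#' conductance' = kappa * (afferent drive) - 2 kappa * conductance -
#' kappa^2 * voltage, where the afferent drive sums intrinsic and
#' extrinsic presynaptic firing weighted by the condition-specific
#' effective gains, and exogenous drive enters the spiny stellate
#' populations of the input targets.
#'
#' @param x state vector of length `8 * n_sources`; entries alternate
#'   (voltage, conductance) per population, sources in declared order
#'   with populations ordered (ss, sp, ii, dp).
#' @param u exogenous drive (scalar, shared across input targets up to
#'   their input gains).
#' @param params a `cmc_params`.
#' @param net a `cmc_network`.
#' @param condition_index which design row's gains to use.
#'
#' @return dx/dt, same length as `x`.
#' @export
cmc_flow <- function(x, u, params, net, condition_index = 1L) {
  if (length(x) != n_states(net)) {
    stop(
      "state vector has length ", length(x), " but the network needs ",
      n_states(net),
      call. = FALSE
    )
  }
  coup <- build_coupling(params, net, condition_index)
  cmc_flow_raw(x, u, coup, params$firing_gain)
}

# Jacobian of the flow at the zero fixed point (linearization), for a
# given condition. Used by stability checks and the linear-response
# oracle in the tests.
cmc_jacobian0 <- function(params, net, condition_index = 1L) {
  coup <- build_coupling(params, net, condition_index)
  np <- length(coup$kappa)
  n <- 2L * np
  vi <- seq(1L, n, by = 2L)
  J <- matrix(0, n, n)
  k <- coup$kappa
  # d voltage'/d conductance = 1
  J[cbind(vi, vi + 1L)] <- 1
  # conductance rows: k * W * f'(0) on voltages - 2k on conductance - k^2 on own voltage
  fp <- params$firing_gain
  J[vi + 1L, vi] <- (k * coup$W) * fp
  J[cbind(vi + 1L, vi)] <- J[cbind(vi + 1L, vi)] - k * k
  J[cbind(vi + 1L, vi + 1L)] <- -2 * k
  J
}
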