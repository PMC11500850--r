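# R-side management of the Gaussian density networks: initialisation, Adam
# updates, and thin wrappers over the compiled forward/backward passes.

# One network: 2 hidden tanh layers, a linear mean head with an optional
# linear skip connection from selected input dims (conditional means are
# near-linear in the physical state, so the skip lets dynamics components
# reach the sensory noise floor instead of spending capacity on an identity
# map), and a softplus variance head floored at var_floor. Inputs outside
# skip_dims influence the mean only through the tanh trunk, whose saturating
# extrapolation keeps predictions inside the trained range -- unfamiliar
# agency values are thereby rejected rather than copied through.
gdn_init <- function(in_dim, out_dim, hidden, var_floor, stream,
                     skip = FALSE, skip_dims = NULL, policy_rows = NULL) {
  mat <- function(nr, nc) {
    matrix(stream_rnorm(stream, nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  }
  # raw bias such that softplus(bv) ~ 0.05: initial predictive sd ~ 0.22,
  # wide enough to cover any workspace-scale residual at initialisation
  W1 <- mat(in_dim, hidden)
  # policy inputs start with zero weight: an untrained component is exactly
  # policy-neutral, so gaze preferences only ever come from learned structure
  if (length(policy_rows)) W1[policy_rows, ] <- 0
  net <- list(W1 = W1, b1 = numeric(hidden),
              W2 = mat(hidden, hidden), b2 = numeric(hidden),
              Wm = mat(hidden, out_dim), bm = numeric(out_dim),
              Wv = mat(hidden, out_dim), bv = rep(-2.9703, out_dim),
              Ws = matrix(0, in_dim, out_dim), skip = skip,
              skip_dims = if (skip) skip_dims else integer(0),
              var_floor = var_floor, in_dim = in_dim, out_dim = out_dim)
  net$adam <- list(t = 0)
  net
}

GDN_PAR <- c("W1", "b1", "W2", "b2", "Wm", "bm", "Wv", "bv", "Ws")

gdn_forward <- function(net, X) {
  .gdn_forward_cpp(net, X)
}

gdn_jvp <- function(net, X, dX) {
  .gdn_jvp_cpp(net, X, dX)
}

# One Adam step from precomputed gradients, with global gradient-norm
# clipping for stability early in training.
adam_apply <- function(net, grads, loss, control) {
  gnorm <- sqrt(sum(vapply(grads, function(m) sum(m^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > control$clip) {
    grads <- lapply(grads, function(m) m * (control$clip / gnorm))
  } else if (!is.finite(gnorm)) {
    return(list(net = net, loss = loss, skipped = TRUE))
  }
  if (!is.null(grads$Ws) && length(net$skip_dims)) {
    masked <- setdiff(seq_len(nrow(grads$Ws)), net$skip_dims)
    grads$Ws[masked, ] <- 0                # restrict the skip to allowed rows
  }
  ad <- net$adam
  ad$t <- ad$t + 1
  lr <- max(control$lr_min,
            control$learning_rate * 0.5^(ad$t / control$lr_halflife))
  b1 <- control$beta1; b2 <- control$beta2
  for (p in names(grads)) {
    if (is.null(ad$m[[p]])) {
      ad$m[[p]] <- grads[[p]] * 0
      ad$v[[p]] <- grads[[p]] * 0
    }
    ad$m[[p]] <- b1 * ad$m[[p]] + (1 - b1) * grads[[p]]
    ad$v[[p]] <- b2 * ad$v[[p]] + (1 - b2) * grads[[p]]^2
    mhat <- ad$m[[p]] / (1 - b1^ad$t)
    vhat <- ad$v[[p]] / (1 - b2^ad$t)
    net[[p]] <- net[[p]] - lr * mhat / (sqrt(vhat) + control$epsilon)
  }
  net$adam <- ad
  list(net = net, loss = loss, skipped = FALSE)
}

# Full mean+variance update (start and end components).
gdn_adam_step <- function(net, X, Y, control) {
  g <- .gdn_nll_grad_cpp(net, X, Y)
  grads <- list(W1 = g$gW1, b1 = drop(g$gb1), W2 = g$gW2, b2 = drop(g$gb2),
                Wm = g$gWm, bm = drop(g$gbm), Wv = g$gWv, bv = drop(g$gbv))
  if (isTRUE(net$skip)) grads$Ws <- g$gWs
  adam_apply(net, grads, g$loss, control)
}

#' Optimiser settings for density-model fitting
#'
#' Fitting minimises the negative log-likelihood of each component's targets
#' by Adam, one update per component per sequence, with gradient-norm
#' clipping.
#'
#' @param learning_rate Initial Adam step size.
#' @param lr_halflife Updates after which the step size has halved (decay is
#'   exponential per update); large step sizes learn the coarse conditional
#'   means quickly, small late steps let the predictive variances settle to
#'   the sensory noise floor.
#' @param lr_min Floor on the decayed step size.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param clip Global gradient-norm clip per update.
#' @param updates_per_sequence Adam steps per component per sequence.
#' @param replay_size,dyn_replay_size Rolling window of recent samples kept
#'   per start/end component and per dynamics component. These components receive only one or two target
#'   rows per sequence, so their update batches are drawn from the most
#'   recent `replay_size` rows; the window preserves recency (the
#'   developmental drift of the stimulus distribution) while making the
#'   variance heads estimable. Dynamics components have hundreds of rows per
#'   sequence and use only the current sequence.
#' @return A `fit_control` list.
#' @export
fit_control <- function(learning_rate = 0.01, lr_halflife = 2000L,
                        lr_min = 3e-4, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, clip = 25, updates_per_sequence = 4L,
                        replay_size = 64L, dyn_replay_size = 1024L) {
  structure(list(learning_rate = learning_rate,
                 lr_halflife = as.integer(lr_halflife), lr_min = lr_min,
                 beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, clip = clip,
                 updates_per_sequence = as.integer(updates_per_sequence),
                 replay_size = as.integer(replay_size),
                 dyn_replay_size = as.integer(dyn_replay_size)),
            class = "fit_control")
}

# Encode policies as one-hot rows in canonical order.
policy_onehot <- function(policies) {
  m <- matrix(0, length(policies), 3L,
              dimnames = list(NULL, POLICIES))
  m[cbind(seq_along(policies), match(policies, POLICIES))] <- 1
  m
}

# Extract (input, target) training batches from a labelled sequence record,
# one batch per (event, kind) with any data:
#   start    targets the first observation of each event, input = policy;
#   dynamics targets o(t) from o(t-1) within an event;
#   end      targets the event's boundary observation (the first observation
#            after the event changed) from every within-event reference
#            observation o(t - kappa), kappa = 1 .. elapsed event length, so
#            the learned end density concentrates on how the event will end
#            rather than on a copy of the reference.
training_batches <- function(record) {
  obs <- record$observations
  lab <- record$event_labels
  pol <- policy_onehot(record$policies)
  len <- nrow(obs)
  out <- list()
  add <- function(event, kind, X, Y) {
    key <- paste(event, kind, sep = ".")
    out[[key]] <<- list(event = event, kind = kind, X = X, Y = Y)
  }
  for (ev in unique(lab)) {
    idx <- which(lab == ev)
    # sequence start or event boundary: first timestep of the event
    starts <- idx[c(TRUE, diff(idx) > 1L)]
    add(ev, "start", pol[starts, , drop = FALSE], obs[starts, , drop = FALSE])
    dyn <- idx[idx > 1L]
    dyn <- dyn[lab[dyn - 1L] == ev]
    if (length(dyn)) {
      add(ev, "dynamics",
          cbind(obs[dyn - 1L, , drop = FALSE], pol[dyn, , drop = FALSE]),
          obs[dyn, , drop = FALSE])
    }
  }
  trans <- which(lab[-1L] != lab[-len]) + 1L
  for (ev in unique(lab[trans - 1L])) {
    X <- NULL; Y <- NULL
    for (tt in trans[lab[trans - 1L] == ev]) {
      run_start <- tt - 1L
      while (run_start > 1L && lab[run_start - 1L] == ev) {
        run_start <- run_start - 1L
      }
      refs <- run_start:(tt - 1L)
      X <- rbind(X, cbind(obs[refs, , drop = FALSE],
                          pol[rep(tt, length(refs)), , drop = FALSE]))
      Y <- rbind(Y, obs[rep(tt, length(refs)), , drop = FALSE])
    }
    add(ev, "end", X, Y)
  }
  out
}
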