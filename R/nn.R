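# Minimal dense-network machinery: parameter init, activations, and an
# Adam/AMSGrad optimizer. All reverse-mode gradients in this package are
# written by hand against these primitives and validated by
# finite-difference tests.

# exponential linear unit; smooth except at 0, C0/C1-adequate for Adam
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# derivative recoverable from the activation value: elu(x) > 0 iff x > 0
elu_deriv_from_act <- function(a) ifelse(a > 0, 1, a + 1)

# linear-layer init matching the common framework default:
# W, b ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_linear <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -bound, bound),
                  fan_in, fan_out),
       b = stats::runif(fan_out, -bound, bound))
}

# clamp log-variance so exp() cannot overflow on extreme inputs; the bound
# is far outside the range reached in normal training
clamp_ls <- function(x, bound = 30) pmin(pmax(x, -bound), bound)

# add a bias vector to every row
addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

# y = act(X W + b); returns the activation (post-nonlinearity) matrix
dense_forward <- function(X, W, b, act = TRUE) {
  A <- addb(X %*% W, b)
  if (act) elu(A) else A
}

# backward through y = act(X W + b) given dY on the *post-activation* output;
# H is the stored activation (used to recover the derivative); for linear
# layers pass act = FALSE and H is ignored
dense_backward <- function(X, H, dY, W, act = TRUE) {
  dA <- if (act) dY * elu_deriv_from_act(H) else dY
  list(dW = crossprod(X, dA),
       db = colSums(dA),
       dX = tcrossprod(dA, W))
}

# Adam with optional AMSGrad and (coupled) L2 weight decay, operating on a
# flat named list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       vhat = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 0.01, weight_decay = 0.01,
                      amsgrad = TRUE,
                      decay_exclude = c("log_beta", "log_gamma")) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    wd <- if (nm %in% decay_exclude) 0 else weight_decay
    g <- grads[[nm]] + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    vv <- if (amsgrad) {
      state$vhat[[nm]] <- pmax(state$vhat[[nm]], state$v[[nm]])
      state$vhat[[nm]]
    } else state$v[[nm]]
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(vv / bc2) + eps)
  }
  list(params = params, state = state)
}
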