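# Adam optimizer over (nested) named lists of numeric arrays.

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  zeros <- function(p) {
    lapply(p, function(x) if (is.list(x)) zeros(x) else
      array(0, dim(x) %||% length(x)))
  }
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zeros(params), v = zeros(params))
}

# One update; returns list(params=, opt=). lr may be overridden per step
# (learning-rate schedules).
adam_step <- function(opt, params, grads, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  walk <- function(p, g, m, v) {
    for (nm in names(p)) {
      if (is.list(p[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        gi <- g[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gi
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gi * gi
        p[[nm]] <- p[[nm]] -
          lr * (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + opt$eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(params = r$p, opt = opt)
}

# Exponential per-epoch decay from lr_start to lr_end over n_epochs.
lr_schedule <- function(epoch, n_epochs, lr_start, lr_end) {
  if (n_epochs <= 1L) return(lr_start)
  frac <- (epoch - 1) / (n_epochs - 1)
  lr_start * (lr_end / lr_start)^frac
}

# Glorot-uniform initialization for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}
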