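# Compact reverse-mode engine for the two networks in this package.
#
# Feature maps are (pixels x channels) matrices in column-major pixel order,
# carrying their spatial extent as attributes "h" and "w". Convolutions are
# im2col gathers followed by a BLAS matrix product; backward passes are
# hand-derived per op and replayed from a tape. Every op is covered by
# finite-difference gradient checks in the test suite.

.geom_cache <- new.env(parent = emptyenv())

.as_fmap <- function(x, h, w, b = 1L) {
  attr(x, "h") <- as.integer(h); attr(x, "w") <- as.integer(w)
  attr(x, "B") <- as.integer(b)
  x
}
.fh <- function(x) attr(x, "h")
.fw <- function(x) attr(x, "w")
.fb <- function(x) { b <- attr(x, "B"); if (is.null(b)) 1L else b }

# replicate a per-image index table across a batch, shifting linear indices
# by the image stride (padding zeros stay zero); cached per geometry
.batch_idx <- function(idx, B, stride, tag = "") {
  if (B == 1L) return(idx)
  key <- paste("b", tag, nrow(idx), ncol(idx), B, stride, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  out <- vector("list", B)
  for (b in seq_len(B)) {
    sh <- idx + (b - 1L) * as.integer(stride)
    sh[idx == 0L] <- 0L
    out[[b]] <- sh
  }
  out <- do.call(rbind, out)
  .geom_cache[[key]] <- out
  out
}

# Linear-index table of the k x k neighborhood of every pixel (0 = padding),
# columns ordered with the row offset fastest; reversing column order negates
# the offset, which backward passes exploit for the flipped-kernel product.
conv_idx <- function(h, w, k) {
  key <- paste("c", h, w, k, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  pd <- (k - 1L) %/% 2L
  ri <- rep(seq_len(h), w); ci <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, k * k)
  j <- 0L
  for (dc in -pd:pd) for (dr in -pd:pd) {
    j <- j + 1L
    rr <- ri + dr; cc <- ci + dc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    idx[, j] <- ifelse(ok, rr + (cc - 1L) * h, 0L)
  }
  .geom_cache[[key]] <- idx
  idx
}

pool_idx <- function(h, w) {
  key <- paste("p", h, w, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  ho <- h %/% 2L; wo <- w %/% 2L
  ro <- rep(seq_len(ho), wo); co <- rep(seq_len(wo), each = ho)
  r0 <- 2L * ro - 1L; c0 <- 2L * co - 1L
  idx <- cbind(r0 + (c0 - 1L) * h, r0 + 1L + (c0 - 1L) * h,
               r0 + c0 * h, r0 + 1L + c0 * h)
  .geom_cache[[key]] <- idx
  idx
}

upsample_idx <- function(h, w) {
  key <- paste("u", h, w, sep = "_")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  ho <- 2L * h; wo <- 2L * w
  ro <- rep(seq_len(ho), wo); co <- rep(seq_len(wo), each = ho)
  v <- ((ro + 1L) %/% 2L) + (((co + 1L) %/% 2L) - 1L) * h
  .geom_cache[[key]] <- v
  v
}

im2col <- function(x, idx) {
  hw <- nrow(idx); k2 <- ncol(idx); C <- ncol(x)
  xp <- rbind(0, x)
  p <- xp[as.vector(idx) + 1L, , drop = FALSE]
  dim(p) <- c(hw, k2 * C)
  p
}

# ---- tape -------------------------------------------------------------------

nn_tape <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list(); tp$ops <- list(); tp$n <- 0L
  tp$params <- params; tp$pids <- list()
  tp
}

.push_val <- function(tp, v) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- v
  tp$n
}

.push_op <- function(tp, rec) tp$ops[[length(tp$ops) + 1L]] <- rec

t_in <- function(tp, x) .push_val(tp, x)

t_param <- function(tp, name) {
  if (!is.null(tp$pids[[name]])) return(tp$pids[[name]])
  v <- tp$params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  id <- .push_val(tp, v)
  tp$pids[[name]] <- id
  id
}

op_conv <- function(tp, x, wname, bname, k) {
  force(x)
  xv <- tp$vals[[x]]; h <- .fh(xv); w <- .fw(xv); B <- .fb(xv)
  idx <- .batch_idx(conv_idx(h, w, k), B, h * w)
  W <- tp$params[[wname]]; b <- tp$params[[bname]]
  p <- im2col(xv, idx)
  y <- p %*% W
  y <- y + rep(b, each = nrow(y))
  y <- .as_fmap(y, h, w, B)
  wi <- t_param(tp, wname); bi <- t_param(tp, bname)
  yi <- .push_val(tp, y)
  # the patch matrix is kept for the backward pass (saves one gather)
  .push_op(tp, list(op = "conv", x = x, wi = wi, bi = bi, y = yi,
                    k = k, h = h, w = w, B = B, p = p))
  yi
}

op_dense <- function(tp, x, wname, bname) {
  force(x)
  xv <- tp$vals[[x]]
  W <- tp$params[[wname]]; b <- tp$params[[bname]]
  y <- xv %*% W + rep(b, each = nrow(xv))
  y <- .as_fmap(y, .fh(xv), .fw(xv), .fb(xv))
  wi <- t_param(tp, wname); bi <- t_param(tp, bname)
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "dense", x = x, wi = wi, bi = bi, y = yi))
  yi
}

op_relu <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]
  y <- .as_fmap(pmax(xv, 0), .fh(xv), .fw(xv), .fb(xv))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "relu", x = x, y = yi))
  yi
}

op_sigmoid <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]
  y <- .as_fmap(1 / (1 + exp(-xv)), .fh(xv), .fw(xv), .fb(xv))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "sigmoid", x = x, y = yi))
  yi
}

op_add <- function(tp, a, b) {
  force(a); force(b)
  av <- tp$vals[[a]]; bv <- tp$vals[[b]]
  y <- .as_fmap(av + bv, .fh(av), .fw(av), .fb(av))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "add", a = a, b = b, y = yi))
  yi
}

op_concat <- function(tp, ids) {
  ids <- lapply(ids, identity)
  vs <- lapply(ids, function(i) tp$vals[[i]])
  y <- do.call(cbind, vs)
  y <- .as_fmap(y, .fh(vs[[1]]), .fw(vs[[1]]), .fb(vs[[1]]))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "concat", ids = ids, y = yi,
                    sizes = vapply(vs, ncol, 0L)))
  yi
}

op_maxpool <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]; h <- .fh(xv); w <- .fw(xv); C <- ncol(xv)
  B <- .fb(xv)
  idx4 <- .batch_idx(pool_idx(h, w), B, h * w)
  hwo <- nrow(idx4)
  y <- matrix(0, hwo, C)
  argsrc <- matrix(0L, hwo, C)
  sq <- seq_len(hwo)
  for (c in seq_len(C)) {
    p4 <- matrix(xv[, c][idx4], hwo, 4)
    a <- max.col(p4, ties.method = "first")
    y[, c] <- p4[cbind(sq, a)]
    argsrc[, c] <- idx4[cbind(sq, a)]
  }
  y <- .as_fmap(y, h %/% 2L, w %/% 2L, B)
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "maxpool", x = x, y = yi, argsrc = argsrc,
                    hw_in = h * w * B))
  yi
}

op_upsample <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]; h <- .fh(xv); w <- .fw(xv); B <- .fb(xv)
  up <- upsample_idx(h, w)
  if (B > 1L) {
    up <- as.vector(vapply(seq_len(B), function(b) up + (b - 1L) * h * w,
                           integer(length(up))))
  }
  y <- .as_fmap(xv[up, , drop = FALSE], 2L * h, 2L * w, B)
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "upsample", x = x, y = yi, up = up,
                    hw_in = h * w * B))
  yi
}

op_gap <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]; B <- .fb(xv)
  hw <- nrow(xv) %/% B
  grp <- rep(seq_len(B), each = hw)
  y <- .as_fmap(rowsum(xv, grp) / hw, 1L, 1L, B)
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "gap", x = x, y = yi, hw = hw, B = B))
  yi
}

op_gmp <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]; B <- .fb(xv); C <- ncol(xv)
  hw <- nrow(xv) %/% B
  y <- matrix(0, B, C)
  arg <- matrix(0L, B, C)
  for (b in seq_len(B)) {
    xb <- xv[((b - 1L) * hw + 1L):(b * hw), , drop = FALSE]
    a <- max.col(t(xb), ties.method = "first")
    arg[b, ] <- a + (b - 1L) * hw
    y[b, ] <- xb[cbind(a, seq_len(C))]
  }
  y <- .as_fmap(y, 1L, 1L, B)
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "gmp", x = x, y = yi, arg = arg, hw = hw * B))
  yi
}

op_chan_mean <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]
  y <- .as_fmap(matrix(rowMeans(xv), ncol = 1), .fh(xv), .fw(xv), .fb(xv))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "chan_mean", x = x, y = yi, C = ncol(xv)))
  yi
}

op_chan_max <- function(tp, x) {
  force(x)
  xv <- tp$vals[[x]]
  arg <- max.col(xv, ties.method = "first")
  y <- .as_fmap(matrix(xv[cbind(seq_len(nrow(xv)), arg)], ncol = 1),
                .fh(xv), .fw(xv), .fb(xv))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "chan_max", x = x, y = yi, arg = arg, C = ncol(xv)))
  yi
}

op_scale_chan <- function(tp, x, s) {
  force(x); force(s)
  xv <- tp$vals[[x]]; sv <- tp$vals[[s]]
  B <- .fb(xv)
  hw <- nrow(xv) %/% B
  S <- sv[rep(seq_len(B), each = hw), , drop = FALSE]
  y <- .as_fmap(xv * S, .fh(xv), .fw(xv), B)
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "scale_chan", x = x, s = s, y = yi, hw = hw, B = B))
  yi
}

op_scale_pix <- function(tp, x, m) {
  force(x); force(m)
  xv <- tp$vals[[x]]; mv <- tp$vals[[m]]
  y <- .as_fmap(xv * as.vector(mv), .fh(xv), .fw(xv), .fb(xv))
  yi <- .push_val(tp, y)
  .push_op(tp, list(op = "scale_pix", x = x, m = m, y = yi))
  yi
}

# ---- backward ---------------------------------------------------------------

nn_backward <- function(tp, out, dout) {
  grads <- vector("list", tp$n)
  if (!is.list(dout)) { out <- list(out); dout <- list(dout) }
  for (i in seq_along(out)) {
    oi <- out[[i]]
    grads[[oi]] <- if (is.null(grads[[oi]])) dout[[i]] else
      grads[[oi]] + dout[[i]]
  }
  acc <- function(i, g) {
    grads[[i]] <<- if (is.null(grads[[i]])) g else grads[[i]] + g
  }
  for (oi in rev(seq_along(tp$ops))) {
    rec <- tp$ops[[oi]]
    dy <- grads[[rec$y]]
    if (is.null(dy)) next
    switch(rec$op,
      conv = {
        xv <- tp$vals[[rec$x]]
        idx <- .batch_idx(conv_idx(rec$h, rec$w, rec$k), rec$B,
                          rec$h * rec$w)
        acc(rec$wi, crossprod(rec$p, dy))
        acc(rec$bi, colSums(dy))
        W <- tp$vals[[rec$wi]]
        k2 <- rec$k * rec$k
        Cin <- ncol(xv); Cout <- ncol(dy)
        Wa <- array(W, c(k2, Cin, Cout))
        Wf <- aperm(Wa[k2:1, , , drop = FALSE], c(1, 3, 2))
        dim(Wf) <- c(k2 * Cout, Cin)
        acc(rec$x, im2col(dy, idx) %*% Wf)
      },
      dense = {
        xv <- tp$vals[[rec$x]]
        acc(rec$wi, crossprod(xv, dy))
        acc(rec$bi, colSums(dy))
        acc(rec$x, dy %*% t(tp$vals[[rec$wi]]))
      },
      relu = acc(rec$x, dy * (tp$vals[[rec$x]] > 0)),
      sigmoid = {
        s <- tp$vals[[rec$y]]
        acc(rec$x, dy * s * (1 - s))
      },
      add = { acc(rec$a, dy); acc(rec$b, dy) },
      concat = {
        off <- 0L
        for (i in seq_along(rec$ids)) {
          sz <- rec$sizes[i]
          acc(rec$ids[[i]], dy[, (off + 1L):(off + sz), drop = FALSE])
          off <- off + sz
        }
      },
      maxpool = {
        C <- ncol(dy)
        dx <- matrix(0, rec$hw_in, C)
        for (c in seq_len(C)) dx[rec$argsrc[, c], c] <- dy[, c]
        acc(rec$x, dx)
      },
      upsample = acc(rec$x, rowsum(dy, rec$up)),
      gap = acc(rec$x, (dy / rec$hw)[rep(seq_len(rec$B), each = rec$hw), ,
                                       drop = FALSE]),
      gmp = {
        dx <- matrix(0, rec$hw, ncol(dy))
        for (b in seq_len(nrow(dy)))
          dx[cbind(rec$arg[b, ], seq_len(ncol(dy)))] <- dy[b, ]
        acc(rec$x, dx)
      },
      chan_mean = acc(rec$x, matrix(dy, nrow(dy), rec$C) / rec$C),
      chan_max = {
        dx <- matrix(0, nrow(dy), rec$C)
        dx[cbind(seq_len(nrow(dy)), rec$arg)] <- as.vector(dy)
        acc(rec$x, dx)
      },
      scale_chan = {
        xv <- tp$vals[[rec$x]]; sv <- tp$vals[[rec$s]]
        S <- sv[rep(seq_len(rec$B), each = rec$hw), , drop = FALSE]
        acc(rec$x, dy * S)
        acc(rec$s, rowsum(dy * xv, rep(seq_len(rec$B), each = rec$hw)))
      },
      scale_pix = {
        xv <- tp$vals[[rec$x]]; mv <- tp$vals[[rec$m]]
        acc(rec$x, dy * as.vector(mv))
        acc(rec$m, matrix(rowSums(dy * xv), ncol = 1))
      },
      stop("unknown op: ", rec$op)
    )
  }
  out <- list()
  for (name in names(tp$pids)) out[[name]] <- grads[[tp$pids[[name]]]]
  out
}

# ---- parameter init & optimizer ---------------------------------------------

he_init <- function(rng, nrow, ncol, fan_in = nrow) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step. Parameters whose gradient is missing or exactly zero are left
# untouched (no moment decay either), so that loss terms switched off by the
# phase indicator leave their heads bit-identical.
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (name in names(params)) {
    g <- grads[[name]]
    if (is.null(g) || !any(g != 0)) next
    state$m[[name]] <- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <- beta2 * state$v[[name]] + (1 - beta2) * g * g
    mh <- state$m[[name]] / b1t
    vh <- state$v[[name]] / b2t
    params[[name]] <- params[[name]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Finite-difference gradient check utility (used by the test suite).
numeric_grad <- function(fn, params, name, eps = 1e-5) {
  p <- params[[name]]
  g <- p * 0
  for (i in seq_along(p)) {
    pp <- params; pp[[name]][i] <- p[i] + eps
    pm <- params; pm[[name]][i] <- p[i] - eps
    g[i] <- (fn(pp) - fn(pm)) / (2 * eps)
  }
  g
}
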