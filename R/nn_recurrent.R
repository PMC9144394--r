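# Recurrent layers with backpropagation through time. Sequences are
# arrays (T, B, D): timesteps x batch x features. Cells follow the
# standard parameterisations (LSTM gates i,f,g,o; GRU gates r,z,n).
# Bidirectional layers run the cell forwards and on the time-reversed
# sequence and concatenate features, doubling the output width.

rnn_cell_init <- function(din, h, cell) {
  mult <- switch(cell, RNN = 1L, GRU = 3L, LSTM = 4L)
  list(Wx = glorot(din, h, c(din, h * mult)),
       Wh = glorot(h, h, c(h, h * mult)),
       b = numeric(h * mult))
}

# X: (T, B, din) -> list(out = (T, B, h), cache)
cell_fwd <- function(p, X, cell) {
  Tn <- dim(X)[1]; B <- dim(X)[2]
  h <- nrow(p$Wh)
  H <- array(0, dim = c(Tn, B, h))
  hs <- matrix(0, B, h)
  cs <- matrix(0, B, h)          # LSTM only
  caches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[t, , ], B)
    if (cell == "RNN") {
      a <- xt %*% p$Wx + hs %*% p$Wh + matrix(p$b, B, h, byrow = TRUE)
      hn <- tanh(a)
      caches[[t]] <- list(xt = xt, hprev = hs, hn = hn)
      hs <- hn
    } else if (cell == "LSTM") {
      a <- xt %*% p$Wx + hs %*% p$Wh + matrix(p$b, B, 4L * h, byrow = TRUE)
      i <- sigmoid(a[, 1:h, drop = FALSE])
      f <- sigmoid(a[, (h + 1):(2 * h), drop = FALSE])
      g <- tanh(a[, (2 * h + 1):(3 * h), drop = FALSE])
      o <- sigmoid(a[, (3 * h + 1):(4 * h), drop = FALSE])
      cn <- f * cs + i * g
      tc <- tanh(cn)
      hn <- o * tc
      caches[[t]] <- list(xt = xt, hprev = hs, cprev = cs, i = i, f = f,
                          g = g, o = o, cn = cn, tc = tc)
      hs <- hn; cs <- cn
    } else { # GRU
      az <- xt %*% p$Wx[, 1:(2 * h), drop = FALSE] +
        hs %*% p$Wh[, 1:(2 * h), drop = FALSE] +
        matrix(p$b[1:(2 * h)], B, 2L * h, byrow = TRUE)
      r <- sigmoid(az[, 1:h, drop = FALSE])
      z <- sigmoid(az[, (h + 1):(2 * h), drop = FALSE])
      an_x <- xt %*% p$Wx[, (2 * h + 1):(3 * h), drop = FALSE] +
        matrix(p$b[(2 * h + 1):(3 * h)], B, h, byrow = TRUE)
      an_h <- hs %*% p$Wh[, (2 * h + 1):(3 * h), drop = FALSE]
      nn <- tanh(an_x + r * an_h)
      hn <- (1 - z) * nn + z * hs
      caches[[t]] <- list(xt = xt, hprev = hs, r = r, z = z, nn = nn,
                          an_h = an_h)
      hs <- hn
    }
    H[t, , ] <- hs
  }
  list(out = H, cache = caches)
}

cell_bwd <- function(p, cache, X, dH, cell) {
  Tn <- dim(dH)[1]; B <- dim(dH)[2]
  h <- nrow(p$Wh)
  din <- nrow(p$Wx)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- array(0, dim = c(Tn, B, din))
  dh_next <- matrix(0, B, h)
  dc_next <- matrix(0, B, h)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- matrix(dH[t, , ], B) + dh_next
    if (cell == "RNN") {
      da <- dh * (1 - cc$hn^2)
      dWx <- dWx + crossprod(cc$xt, da)
      dWh <- dWh + crossprod(cc$hprev, da)
      db <- db + colSums(da)
      dX[t, , ] <- tcrossprod(da, p$Wx)
      dh_next <- tcrossprod(da, p$Wh)
    } else if (cell == "LSTM") {
      do <- dh * cc$tc * cc$o * (1 - cc$o)
      dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
      di <- dc * cc$g * cc$i * (1 - cc$i)
      df <- dc * cc$cprev * cc$f * (1 - cc$f)
      dg <- dc * cc$i * (1 - cc$g^2)
      dc_next <- dc * cc$f
      da <- cbind(di, df, dg, do)
      dWx <- dWx + crossprod(cc$xt, da)
      dWh <- dWh + crossprod(cc$hprev, da)
      db <- db + colSums(da)
      dX[t, , ] <- tcrossprod(da, p$Wx)
      dh_next <- tcrossprod(da, p$Wh)
    } else { # GRU
      dz <- dh * (cc$hprev - cc$nn) * cc$z * (1 - cc$z)
      dn <- dh * (1 - cc$z)
      dan <- dn * (1 - cc$nn^2)
      dr <- dan * cc$an_h * cc$r * (1 - cc$r)
      da_rz <- cbind(dr, dz)
      Wx_rz <- p$Wx[, 1:(2 * h), drop = FALSE]
      Wh_rz <- p$Wh[, 1:(2 * h), drop = FALSE]
      Wx_n <- p$Wx[, (2 * h + 1):(3 * h), drop = FALSE]
      Wh_n <- p$Wh[, (2 * h + 1):(3 * h), drop = FALSE]
      dWx[, 1:(2 * h)] <- dWx[, 1:(2 * h)] + crossprod(cc$xt, da_rz)
      dWh[, 1:(2 * h)] <- dWh[, 1:(2 * h)] + crossprod(cc$hprev, da_rz)
      db[1:(2 * h)] <- db[1:(2 * h)] + colSums(da_rz)
      dWx[, (2 * h + 1):(3 * h)] <- dWx[, (2 * h + 1):(3 * h)] +
        crossprod(cc$xt, dan)
      dWh[, (2 * h + 1):(3 * h)] <- dWh[, (2 * h + 1):(3 * h)] +
        crossprod(cc$hprev, dan * cc$r)
      db[(2 * h + 1):(3 * h)] <- db[(2 * h + 1):(3 * h)] + colSums(dan)
      dX[t, , ] <- tcrossprod(da_rz, Wx_rz) + tcrossprod(dan, Wx_n)
      dh_next <- dh * cc$z + tcrossprod(da_rz, Wh_rz) +
        tcrossprod(dan * cc$r, Wh_n)
    }
  }
  list(dx = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

rev_time <- function(X) {
  X[rev(seq_len(dim(X)[1])), , , drop = FALSE]
}

# bidirectional wrapper: params = list(fwd = ..., bwd = ...)
bicell_fwd <- function(p, X, cell) {
  f <- cell_fwd(p$fwd, X, cell)
  Xr <- rev_time(X)
  b <- cell_fwd(p$bwd, Xr, cell)
  Hb <- rev_time(b$out)
  Tn <- dim(X)[1]; B <- dim(X)[2]
  h <- dim(f$out)[3]
  H <- array(0, dim = c(Tn, B, 2L * h))
  H[, , 1:h] <- f$out
  H[, , (h + 1):(2 * h)] <- Hb
  list(out = H, cache = list(f = f$cache, b = b$cache, Xr = Xr, h = h))
}

bicell_bwd <- function(p, cache, X, dH, cell) {
  h <- cache$h
  df <- cell_bwd(p$fwd, cache$f, X, dH[, , 1:h, drop = FALSE], cell)
  db <- cell_bwd(p$bwd, cache$b, cache$Xr,
                 rev_time(dH[, , (h + 1):(2 * h), drop = FALSE]), cell)
  list(dx = df$dx + rev_time(db$dx),
       grads = list(fwd = df$grads, bwd = db$grads))
}
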