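# Shared fixtures and independent oracles for the test suite.

# Small configs keep unit tests fast; the acceptance tests use the
# reference configuration where the contract demands it.
tiny_cfg <- function(patch = 16L, ...) {
  network_config(semantic_widths = c(3L, 4L, 6L), detail_width = 3L,
                 patch_size = patch, ...)
}

small_spec <- function(...) {
  phantom_spec(volume_shape = c(48L, 48L, 48L), ...)
}

rand_mask <- function(dm, p = 0.3) {
  array(as.integer(runif(prod(dm)) < p), dm)
}

# Independent connected-component oracle: iterative minimum-label
# propagation over the 26-neighbourhood, no shared code with the BFS
# labeller under test.
flood_fill_labels <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lab <- array(0, dm)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  offs <- offs[!(offs$a == 0 & offs$b == 0 & offs$c == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$a) + abs(offs$b) + abs(offs$c) == 1, ]
  shift_pad <- function(a, off) {
    out <- array(Inf, dm)
    src <- lapply(1:3, function(i) {
      idx <- seq_len(dm[i]) + off[[i]]
      idx[idx >= 1 & idx <= dm[i]]
    })
    dst <- lapply(1:3, function(i) {
      idx <- seq_len(dm[i])
      idx[idx + off[[i]] >= 1 & idx + off[[i]] <= dm[i]]
    })
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  lab[mask == 0] <- Inf
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      sh <- shift_pad(lab, offs[r, ])
      new <- pmin(new, sh)
    }
    new[mask == 0] <- Inf
    if (all(new[mask != 0] == lab[mask != 0])) break
    lab <- new
  }
  out <- array(0L, dm)
  fg <- mask != 0
  out[fg] <- as.integer(match(lab[fg], sort(unique(lab[fg]))))
  out
}

# Component voxel-size table from any labelling (invariant to label ids).
component_sizes <- function(lab) sort(tabulate(lab[lab > 0L]))

# Closed-form parameter count of the reference architecture, written out
# block by block (independent of the package's shape enumeration).
closed_form_param_count <- function(C1, C2, C3, Cd, nc = 2L, ic = 1L) {
  cb <- function(cin, cout, k = 3) k^3 * cin * cout + 2 * cout
  tb <- function(cin, cout) 8 * cin * cout + 2 * cout
  lg <- function(cin, cout) 27 * cin * cout + cout
  stage <- function(cin, cout) cb(cin, cout) + 2 * cb(cout, cout)
  sem <- stage(ic, C1) + stage(C1, C2) + stage(C2, C3)
  det <- stage(ic, Cd) + stage(Cd, Cd) + stage(Cd, Cd)
  cfm <- cb(Cd, C2) + cb(C2, Cd) + tb(Cd, Cd) +            # stage-2 exchange
    cb(Cd, Cd) + cb(Cd, C3) + cb(C3, Cd) + 2 * tb(Cd, Cd)  # stage-3 exchange
  dam <- cb(Cd, Cd, 1) + cb(Cd, Cd, 3) + cb(Cd, Cd, 5) + cb(Cd, Cd, 7) +
    cb(Cd, Cd, 1)
  dec <- tb(C3, Cd) + tb(Cd, Cd) + lg(Cd, nc)
  aux <- tb(C3, Cd) + tb(Cd, Cd) + lg(Cd, nc) + lg(Cd, nc)
  sem + det + cfm + dam + dec + aux
}
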