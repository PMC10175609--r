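#' Anatomically constrained connectivity mask of the CL1a-CL2 network
#'
#' The network holds 32 neurons: 16 CL1a (state components 1-16) and 16 CL2
#' (components 17-32), each tied to one PB column `L8 ... R8`. The mask marks
#' which synapses the reported arborization patterns permit; optimization
#' only assigns weights to masked-in entries. Entry `(i, j)` allows a
#' connection from neuron `j` onto neuron `i` (states evolve as
#' `x[t+1] = M x[t]`).
#'
#' * CL1a -> CL2 (in the PB): same PB column only — no arborizations broader
#'   than one column occur in the PB.
#' * CL1a -> CL1a and CL2 -> CL2: self-connection plus the two adjacent PB
#'   columns, supporting a baseline-maintaining local recurrence. Positions
#'   1 (`L8`) and 16 (`R8`) are not adjacent: the PB is an open structure
#'   with no anatomical ring closure.
#' * CL2 -> CL1a (in the CBL): CL1a ramifications span up to five columns,
#'   realized as a band of half-width `cbl_bandwidth` (default 2) around the
#'   same-column diagonal and around the mirror-column (anti-)diagonal, the
#'   latter capturing the intercalated contralateral projection scheme.
#' * `variant = "noduli"` additionally allows every same-hemisphere
#'   CL2 -> CL2 pair, modeling putative interconnections within the lower
#'   units of the noduli.
#'
#' @param variant `"default"` or `"noduli"`.
#' @param cbl_bandwidth Half-width of the two CL2 -> CL1a bands in columns.
#' @return A 32 x 32 logical matrix of class `connectivity_mask` with
#'   neuron dimnames and attributes `variant` and `cbl_bandwidth`.
#' @examples
#' m <- build_mask()
#' sum(m[17:32, 1:16])  # 16: the identity pattern of CL1a -> CL2
#' @export
build_mask <- function(variant = c("default", "noduli"), cbl_bandwidth = 2L) {
  variant <- match.arg(variant)
  mask <- matrix(FALSE, 32, 32)
  for (i in 1:16) for (j in 1:16) {
    adjacent <- abs(i - j) <= 1                 # open PB: no 1<->16 wrap
    mask[i, j] <- adjacent                      # CL1a -> CL1a
    mask[16 + i, 16 + j] <- adjacent            # CL2  -> CL2
    mask[16 + i, j] <- i == j                   # CL1a -> CL2, same column
    mask[i, 16 + j] <- abs(i - j) <= cbl_bandwidth ||
      abs(i - mirror_position(j)) <= cbl_bandwidth  # CL2 -> CL1a, two bands
  }
  if (variant == "noduli")
    for (i in 1:16) for (j in 1:16)
      if ((i <= 8) == (j <= 8)) mask[16 + i, 16 + j] <- TRUE
  nm <- c(paste0("CL1a_", pb_columns()), paste0("CL2_", pb_columns()))
  dimnames(mask) <- list(nm, nm)
  structure(mask, variant = variant, cbl_bandwidth = as.integer(cbl_bandwidth),
            class = c("connectivity_mask", class(mask)))
}

#' @export
print.connectivity_mask <- function(x, ...) {
  cat(sprintf("CL1a-CL2 connectivity mask ('%s' variant): %d of %d synapses allowed\n",
              attr(x, "variant"), sum(x), length(x)))
  invisible(x)
}

#' Sinusoidal compass-bump target states
#'
#' One target per PB column: the CL1a activity profile
#' \eqn{\hat x_c(j) = \cos(2\pi (j - c) / n)} places a single activity
#' maximum ("compass bump") in column `c` with one full period across the
#' PB — a single 360 degree representation of azimuth — and the CL2
#' subvector duplicates the CL1a subvector. All targets are cyclic shifts
#' of one mother profile and sum to zero across columns (activity is a
#' deviation from baseline firing).
#'
#' @param n_columns Number of PB columns (>= 4; the biological value is 16).
#' @param profile Bump profile; `"cosine"` is the only built-in.
#' @return A `2 * n_columns` x `n_columns` matrix of class `target_set`;
#'   column `c` is the target state with the bump in PB column `c`.
#' @examples
#' X <- make_targets()
#' which.max(X[1:16, 1])  # bump of the first target sits at position 1 (L8)
#' @export
make_targets <- function(n_columns = 16, profile = c("cosine")) {
  profile <- match.arg(profile)
  if (n_columns < 4) stop("n_columns must be >= 4")
  half <- vapply(seq_len(n_columns),
                 function(cc) cos(2 * pi * (seq_len(n_columns) - cc) / n_columns),
                 numeric(n_columns))
  X <- rbind(half, half)
  if (n_columns == 16)
    dimnames(X) <- list(c(paste0("CL1a_", pb_columns()), paste0("CL2_", pb_columns())),
                        pb_columns())
  structure(X, class = c("target_set", class(X)))
}

# bump column after one time step of turning: a LEFT turn shifts the bump
# one position toward higher index (rightward along L8 -> R8), cyclically.
shift_column <- function(position, direction, n_columns = 16) {
  if (direction == "left") (position %% n_columns) + 1L
  else ((position - 2L) %% n_columns) + 1L
}

#' Locate the compass bump in a network state
#'
#' Returns the PB position of the activity maximum of the chosen
#' subpopulation. Ties within `tol` are broken toward the lower position and
#' flagged via the `degenerate` attribute; a state with all-equal
#' subpopulation activity has no bump and is an error. The position is
#' invariant to positive rescaling of the state.
#'
#' @param x Network state: numeric vector of length 32 (components 1-16
#'   CL1a, 17-32 CL2).
#' @param population `"CL1a"` or `"CL2"`.
#' @param tol Tie tolerance.
#' @return Integer position in 1..16, named with the PB column label, with
#'   attribute `degenerate`.
#' @examples
#' bump_position(make_targets()[, 5])  # position 5, column "L4"
#' @export
bump_position <- function(x, population = c("CL1a", "CL2"), tol = 1e-8) {
  population <- match.arg(population)
  stopifnot(length(x) == 32)
  v <- if (population == "CL1a") x[1:16] else x[17:32]
  if (diff(range(v)) <= tol) stop("degenerate state: no unique activity maximum")
  p <- which.max(v)  # which.max already breaks exact ties toward lower index
  degenerate <- sum(v >= v[p] - tol) > 1
  structure(stats::setNames(as.integer(p), pb_columns()[p]), degenerate = degenerate)
}
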