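## Channel-resolved electron-water cross sections: data model, TSV format,
## interpolation and stochastic sampling.

CHANNEL_KINDS <- c("elastic", "ionisation", "excitation_discrete",
                   "excitation_collective", "vibrational", "phonon",
                   "attachment")
LOSS_MODELS <- c("none", "fixed_quantum", "differential_table")

## integer codes handed to the C++ engine (0-based)
.kind_code <- function(kind) match(kind, CHANNEL_KINDS) - 1L

#' Define a collision channel
#'
#' A channel couples an electron to one interaction pathway of the water
#' molecule: elastic scattering, ionisation of a shell, a discrete electronic
#' excitation, the collective (plasmon-like) excitation that dominates the
#' liquid-phase energy-loss function, a vibrational mode, quasi-elastic
#' phonon scattering, or dissociative electron attachment (DEA, disabled by
#' default).
#'
#' @param name short unique label.
#' @param kind one of `"elastic"`, `"ionisation"`, `"excitation_discrete"`,
#'   `"excitation_collective"`, `"vibrational"`, `"phonon"`, `"attachment"`.
#' @param threshold_energy eV. Ionisation binding energy, excitation
#'   transition onset, or vibrational quantum; 0 for elastic/phonon.
#' @param energy_loss_model `"none"` (elastic), `"fixed_quantum"`
#'   (excitation, vibrational, phonon) or `"differential_table"`
#'   (ionisation; secondary energy drawn from a truncated Lorentzian-tail
#'   differential model).
#' @param transfer eV; the fixed energy quantum transferred per collision for
#'   `fixed_quantum` channels. Defaults to `threshold_energy`. For the
#'   collective excitation the transfer (transition energy) exceeds the
#'   threshold (binding) and the difference is carried away by the tracked
#'   electron.
#' @param lorentz_a eV; width parameter of the differential secondary-energy
#'   model \eqn{d\sigma/dW \propto 1/(W^2+a^2)} for ionisation channels.
#' @return an object of class `aq_channel`.
#' @export
xsec_channel <- function(name, kind, threshold_energy,
                         energy_loss_model = NULL,
                         transfer = threshold_energy,
                         lorentz_a = 8) {
  kind <- match.arg(kind, CHANNEL_KINDS)
  if (is.null(energy_loss_model)) {
    energy_loss_model <- switch(kind,
      elastic = "none", ionisation = "differential_table", "fixed_quantum")
  }
  energy_loss_model <- match.arg(energy_loss_model, LOSS_MODELS)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(threshold_energy) || threshold_energy < 0)
    stop("threshold_energy must be >= 0", call. = FALSE)
  if (transfer < threshold_energy && kind != "ionisation")
    stop("transfer must be >= threshold_energy", call. = FALSE)
  structure(list(name = name, kind = kind,
                 threshold_energy = threshold_energy,
                 energy_loss_model = energy_loss_model,
                 transfer = transfer, lorentz_a = lorentz_a),
            class = "aq_channel")
}

#' Assemble a cross-section table
#'
#' @param energy_eV strictly ascending energy grid, eV.
#' @param sigma matrix (length(energy_eV) x n channels) of cross sections in
#'   nm^2, columns named after the channels.
#' @param channels list of [xsec_channel()] objects, in column order.
#' @param number_density molecules per nm^3 (33.43 for liquid water at
#'   1 g/cm^3).
#' @param phase `"liquid"` or `"vapour"`.
#' @param provenance free-text provenance string stored with the table.
#' @param dea_zero enforce the default-physics invariant that attachment
#'   channels carry zero cross section (see [validate_xsec()]).
#' @return an object of class `aq_xsec`.
#' @export
xsec_table <- function(energy_eV, sigma, channels,
                       number_density = aq_constants$n_water,
                       phase = c("liquid", "vapour"),
                       provenance = "", dea_zero = TRUE) {
  phase <- match.arg(phase)
  sigma <- as.matrix(sigma)
  if (length(channels) != ncol(sigma))
    stop("one sigma column per channel required", call. = FALSE)
  colnames(sigma) <- vapply(channels, `[[`, "", "name")
  tab <- structure(list(energy_eV = as.numeric(energy_eV), sigma = sigma,
                        channels = channels,
                        number_density = number_density,
                        phase = phase, provenance = provenance),
                   class = "aq_xsec")
  validate_xsec(tab, require_dea_zero = dea_zero)
  tab
}

#' Validate a cross-section table
#'
#' Checks all structural invariants: a strictly increasing energy grid,
#' non-negative cross sections, zero cross section below each channel
#' threshold, presence of at least one elastic and one ionisation channel,
#' and zero cross section on attachment (DEA) channels.
#'
#' @param table an `aq_xsec` object.
#' @param require_dea_zero if `TRUE` (default) attachment channels must carry
#'   an all-zero cross-section column; DEA is disabled in the default
#'   physics and can only be enabled explicitly in the run configuration.
#' @return the table, invisibly; stops with an informative error otherwise.
#' @export
validate_xsec <- function(table, require_dea_zero = TRUE) {
  E <- table$energy_eV
  if (length(E) < 2L || any(diff(E) <= 0))
    stop("energy grid not strictly increasing (row ",
         which(diff(E) <= 0)[1] + 1L, ")", call. = FALSE)
  s <- table$sigma
  if (nrow(s) != length(E))
    stop("sigma rows do not match energy grid", call. = FALSE)
  bad <- which(!is.finite(s) | s < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite cross section at row ", bad[1, 1],
         ", column '", colnames(s)[bad[1, 2]], "'", call. = FALSE)
  kinds <- vapply(table$channels, `[[`, "", "kind")
  if (!any(kinds == "elastic"))
    stop("table must contain an elastic channel", call. = FALSE)
  if (!any(kinds == "ionisation"))
    stop("table must contain an ionisation channel", call. = FALSE)
  for (j in seq_along(table$channels)) {
    ch <- table$channels[[j]]
    below <- E < ch$threshold_energy
    if (any(s[below, j] > 0))
      stop("channel '", ch$name, "' has sigma > 0 below its threshold (row ",
           which(below & s[, j] > 0)[1], ")", call. = FALSE)
    if (require_dea_zero && ch$kind == "attachment" && any(s[, j] != 0))
      stop("attachment channel '", ch$name,
           "' must carry zero cross section (DEA disabled)", call. = FALSE)
  }
  if (anyDuplicated(colnames(s)))
    stop("duplicate channel names", call. = FALSE)
  invisible(table)
}

#' @export
print.aq_xsec <- function(x, ...) {
  cat("<aq_xsec> ", x$phase, " water, ", length(x$channels), " channels, ",
      length(x$energy_eV), " grid points [",
      format(min(x$energy_eV)), ", ", format(max(x$energy_eV)), "] eV\n",
      sep = "")
  for (ch in x$channels)
    cat(sprintf("  %-12s %-22s thr=%g eV  loss=%s\n", ch$name, ch$kind,
                ch$threshold_energy, ch$energy_loss_model))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------- TSV I/O

#' Read / write the cross-section TSV format
#'
#' The on-disk dialect is plain TSV with header comment lines:
#' `#phase=liquid`, `#density_nm3=33.43`, `#provenance=...`, one
#' `#channel <name> <kind> <threshold_eV> <loss_model> [key=value ...]` line
#' per channel, then data rows `E_eV<TAB>sigma_nm2_...` in channel order.
#' Numbers are written with 17 significant digits so a write/read cycle is
#' bit-exact.
#'
#' @param path file path.
#' @return [read_xsec()] returns a validated `aq_xsec`; [write_xsec()]
#'   returns `path` invisibly.
#' @export
read_xsec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_kv <- function(key, default = NULL) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    sub(paste0("^#", key, "="), "", m[1])
  }
  phase <- get_kv("phase", "liquid")
  dens <- as.numeric(get_kv("density_nm3", aq_constants$n_water))
  prov <- get_kv("provenance", "")
  chlines <- grep("^#channel ", hdr, value = TRUE)
  if (length(chlines) == 0) stop("no #channel declarations", call. = FALSE)
  channels <- lapply(chlines, function(l) {
    tok <- strsplit(sub("^#channel ", "", l), "[[:space:]]+")[[1]]
    if (length(tok) < 4) stop("malformed channel line: ", l, call. = FALSE)
    extra <- tok[-(1:4)]
    kv <- list()
    for (e in extra) {
      p <- strsplit(e, "=", fixed = TRUE)[[1]]
      kv[[p[1]]] <- as.numeric(p[2])
    }
    xsec_channel(tok[1], tok[2], as.numeric(tok[3]), tok[4],
                 transfer = if (!is.null(kv$transfer)) kv$transfer
                            else as.numeric(tok[3]),
                 lorentz_a = if (!is.null(kv$lorentz_a)) kv$lorentz_a else 8)
  })
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol_expect <- length(channels) + 1L
  nf <- lengths(fields)
  if (any(nf != ncol_expect))
    stop("row ", which(nf != ncol_expect)[1], " has ", nf[nf != ncol_expect][1],
         " fields, expected ", ncol_expect, call. = FALSE)
  num <- matrix(as.numeric(unlist(fields)), ncol = ncol_expect, byrow = TRUE)
  if (anyNA(num)) stop("non-numeric entry in data rows", call. = FALSE)
  xsec_table(num[, 1], num[, -1, drop = FALSE], channels,
             number_density = dens, phase = phase, provenance = prov)
}

#' @param table an `aq_xsec` object.
#' @rdname read_xsec
#' @export
write_xsec <- function(table, path) {
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(paste0("#phase=", table$phase),
           paste0("#density_nm3=", num(table$number_density)),
           paste0("#provenance=", table$provenance))
  for (ch in table$channels) {
    extra <- character()
    if (ch$transfer != ch$threshold_energy)
      extra <- c(extra, paste0("transfer=", num(ch$transfer)))
    if (ch$kind == "ionisation")
      extra <- c(extra, paste0("lorentz_a=", num(ch$lorentz_a)))
    hdr <- c(hdr, paste("#channel", ch$name, ch$kind,
                        num(ch$threshold_energy), ch$energy_loss_model,
                        paste(extra, collapse = " ")))
  }
  hdr <- sub("[[:space:]]+$", "", hdr)
  rows <- apply(cbind(table$energy_eV, table$sigma), 1,
                function(r) paste(num(r), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

## ------------------------------------------------------ interpolation etc.

.channel_index <- function(table, channel) {
  if (inherits(channel, "aq_channel")) channel <- channel$name
  if (is.character(channel)) {
    j <- match(channel, colnames(table$sigma))
    if (is.na(j)) stop("no channel named '", channel, "'", call. = FALSE)
    return(j)
  }
  as.integer(channel)
}

#' Interpolated cross section of one channel
#'
#' Log-log linear interpolation between bracketing grid nodes (cross
#' sections span many decades); exact at grid nodes; zero below the channel
#' threshold. If either bracketing node is zero the interpolation falls back
#' to linear so channels containing zeros remain well defined. Queries above
#' the grid maximum are an error: no extrapolation.
#'
#' @param table an `aq_xsec`.
#' @param channel channel name, index, or `aq_channel`.
#' @param E energies, eV (vectorised).
#' @return cross sections, nm^2.
#' @export
sigma_at <- function(table, channel, E) {
  j <- .channel_index(table, channel)
  grid <- table$energy_eV
  if (any(E > grid[length(grid)] * (1 + 1e-12)))
    stop("energy above grid maximum (", format(grid[length(grid)]),
         " eV); no extrapolation", call. = FALSE)
  thr <- table$channels[[j]]$threshold_energy
  s <- table$sigma[, j]
  out <- numeric(length(E))
  for (k in seq_along(E)) {
    e <- E[k]
    if (e < thr || e < grid[1]) next
    i <- findInterval(e, grid, rightmost.closed = TRUE)
    if (grid[i] == e) { out[k] <- s[i]; next }
    s1 <- s[i]; s2 <- s[i + 1]
    if (s1 > 0 && s2 > 0) {
      f <- (log(e) - log(grid[i])) / (log(grid[i + 1]) - log(grid[i]))
      out[k] <- exp(log(s1) + f * (log(s2) - log(s1)))
    } else {
      out[k] <- s1 + (e - grid[i]) / (grid[i + 1] - grid[i]) * (s2 - s1)
    }
  }
  out
}

#' Inverse mean free path
#'
#' \eqn{\Lambda(E) = n \sum_c \sigma_c(E)} with `n` the molecular number
#' density; the mean free path is `1/inverse_mfp(...)`.
#'
#' @inheritParams sigma_at
#' @return nm^-1 (vectorised over `E`).
#' @export
inverse_mfp <- function(table, E) {
  tot <- numeric(length(E))
  for (j in seq_along(table$channels)) tot <- tot + sigma_at(table, j, E)
  table$number_density * tot
}

#' Sample exponential free-flight lengths
#'
#' Flight lengths between collisions are exponential with rate
#' \eqn{\Lambda(E)}. Uses R's global RNG stream (seed with [set.seed()]).
#'
#' @inheritParams sigma_at
#' @param E single energy, eV.
#' @param n number of draws.
#' @return flight lengths, nm.
#' @export
sample_flight <- function(table, E, n = 1) {
  lam <- inverse_mfp(table, E)
  if (lam <= 0)
    stop("no interaction possible: inverse mean free path is zero",
         call. = FALSE)
  stats::rexp(n, rate = lam)
}

#' Sample the collision channel at energy E
#'
#' Channel `c` is drawn with probability \eqn{\sigma_c(E)/\sum\sigma(E)}.
#'
#' @inheritParams sample_flight
#' @return character vector of channel names.
#' @export
sample_channel <- function(table, E, n = 1) {
  sig <- vapply(seq_along(table$channels),
                function(j) sigma_at(table, j, E), numeric(1))
  tot <- sum(sig)
  if (tot <= 0) stop("all cross sections zero at E = ", E, call. = FALSE)
  nm <- colnames(table$sigma)
  nm[sample.int(length(sig), n, replace = TRUE, prob = sig / tot)]
}

#' Sample the energy partition of one collision
#'
#' Implements the per-kind energy-transfer rules. Ionisation transfers the
#' binding energy plus the ejected-electron kinetic energy `W`, with `W`
#' drawn from the truncated Lorentzian-tail differential model
#' \eqn{d\sigma/dW \propto 1/(W^2 + a^2)} on `[0, (E - B)/2]` (the upper
#' bound reflects indistinguishability of the outgoing electrons).
#' Excitations transfer the fixed transition energy and hand
#' `max(0, transfer - threshold)` to the tracked electron. Vibrational and
#' phonon channels transfer their fixed quantum and free no electron.
#' Elastic collisions transfer essentially nothing (recoil is neglected).
#'
#' @param channel an `aq_channel`.
#' @param E projectile kinetic energy, eV.
#' @return list with `energy_transfer`, `secondary_KE` (eV; `NA` when no
#'   electron is freed) and `spawns_electron` (logical).
#' @export
sample_energy_partition <- function(channel, E) {
  k <- channel$kind
  thr <- channel$threshold_energy
  if (k == "elastic")
    return(list(energy_transfer = 0, secondary_KE = NA_real_,
                spawns_electron = FALSE))
  need <- if (k == "ionisation") thr else channel$transfer
  if (E <= need)
    stop("projectile energy ", E, " eV not above channel threshold ",
         need, " eV", call. = FALSE)
  if (k == "ionisation") {
    wmax <- (E - thr) / 2
    a <- channel$lorentz_a
    w <- a * tan(stats::runif(1) * atan(wmax / a))  # inverse CDF
    return(list(energy_transfer = thr + w, secondary_KE = w,
                spawns_electron = TRUE))
  }
  if (k %in% c("excitation_discrete", "excitation_collective")) {
    tr <- channel$transfer
    return(list(energy_transfer = tr,
                secondary_KE = max(0, tr - thr), spawns_electron = TRUE))
  }
  if (k %in% c("vibrational", "phonon"))
    return(list(energy_transfer = channel$transfer, secondary_KE = NA_real_,
                spawns_electron = FALSE))
  ## attachment: the projectile is absorbed
  list(energy_transfer = E, secondary_KE = NA_real_, spawns_electron = FALSE)
}

## Flatten a table into the plain numeric structure consumed by the engine.
.xsec_compact <- function(table) {
  chans <- table$channels
  list(E = table$energy_eV,
       logE = log(table$energy_eV),
       sig = table$sigma,
       kind = vapply(chans, function(c) .kind_code(c$kind), integer(1)),
       thr = vapply(chans, `[[`, 0, "threshold_energy"),
       transfer = vapply(chans, `[[`, 0, "transfer"),
       lor_a = vapply(chans, `[[`, 0, "lorentz_a"),
       dens = table$number_density)
}
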