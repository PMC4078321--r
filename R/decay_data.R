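#' Non-radiative emission spectra
#'
#' A non-radiative (NR) spectrum describes the electron emissions of one decay:
#' grouped Auger/Coster-Kronig electrons (AE) and internal conversion electron
#' (CE) lines with initial kinetic energies of at least 1 keV, beta branches,
#' and the mean energy per decay carried by sub-1-keV AE, which is treated as
#' deposited locally at the decay site. Curated spectra for I-123, I-125 and
#' I-131 are shipped with the package; synthetic nuclides for validation are
#' built with [make_toy_nuclide()].
#'
#' @param nuclide_id Nuclide identifier, e.g. `"I-125"`, or the id of a
#'   registered toy nuclide.
#' @return An object of class `nr_spectrum`: a list with elements
#'   `nuclide_id`, `half_life_s`, `lines` (data frame `kind`, `energy_keV`,
#'   `yield`), `beta_branches` (data frame `endpoint_keV`, `yield`, `shape`,
#'   `daughter_Z`), `local_energy_sub1kev` (keV per decay) and
#'   `n_sub1kev_ae` (expected sub-1-keV AE count per decay).
#' @examples
#' sp <- load_spectrum("I-125")
#' mean_energy_per_decay(sp)
#' @export
load_spectrum <- function(nuclide_id) {
  stopifnot(is.character(nuclide_id), length(nuclide_id) == 1L)
  reg <- toy_registry()
  if (!is.null(reg[[nuclide_id]])) {
    return(reg[[nuclide_id]])
  }
  cache <- .thyrodose_env$spectra
  if (is.null(cache)) {
    cache <- list()
  }
  if (!is.null(cache[[nuclide_id]])) {
    return(cache[[nuclide_id]])
  }
  fname <- paste0("spectrum_", gsub("-", "", nuclide_id), ".tsv")
  path <- system.file("extdata", fname, package = "thyrodose")
  if (!nzchar(path)) {
    stop("nuclide not registered: ", nuclide_id)
  }
  sp <- read_spectrum_file(path, nuclide_id)
  cache[[nuclide_id]] <- sp
  .thyrodose_env$spectra <- cache
  sp
}

read_spectrum_file <- function(path, nuclide_id) {
  hdr_lines <- grep("^#", readLines(path, n = 20L), value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    hdr[[key]] <- val
  }
  tab <- read.table(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  lines <- tab[tab$kind %in% c("AE", "CE"), c("kind", "energy_keV", "yield")]
  rownames(lines) <- NULL
  bet <- tab[tab$kind == "BETA", , drop = FALSE]
  beta_branches <- data.frame(
    endpoint_keV = bet$energy_keV,
    yield = bet$yield,
    shape = if (nrow(bet)) bet$shape else character(0),
    daughter_Z = if (nrow(bet)) as.integer(hdr$daughter_Z) else integer(0),
    stringsAsFactors = FALSE
  )
  new_nr_spectrum(
    nuclide_id = nuclide_id,
    lines = lines,
    beta_branches = beta_branches,
    local_energy_sub1kev = as.numeric(hdr$local_energy_sub1kev_keV),
    n_sub1kev_ae = as.numeric(hdr$n_sub1kev_ae),
    half_life_s = as.numeric(hdr$half_life_s)
  )
}

new_nr_spectrum <- function(nuclide_id, lines, beta_branches,
                            local_energy_sub1kev, n_sub1kev_ae = 0,
                            half_life_s = NA_real_) {
  lines <- as.data.frame(lines)
  if (nrow(lines)) {
    if (any(!lines$kind %in% c("AE", "CE"))) {
      stop("line kind must be 'AE' or 'CE'")
    }
    if (any(lines$energy_keV <= 0)) stop("line energies must be positive")
    if (any(lines$yield < 0)) stop("line yields must be non-negative")
    if (any(lines$energy_keV < 1)) {
      stop("lines below 1 keV belong in local_energy_sub1kev")
    }
  }
  beta_branches <- as.data.frame(beta_branches)
  if (nrow(beta_branches)) {
    if (any(beta_branches$endpoint_keV <= 0)) {
      stop("beta endpoint energies must be positive")
    }
    if (any(beta_branches$yield < 0 | beta_branches$yield > 1)) {
      stop("beta branch yields must lie in [0, 1]")
    }
  }
  if (local_energy_sub1kev < 0) stop("local_energy_sub1kev must be >= 0")
  structure(
    list(nuclide_id = nuclide_id,
         half_life_s = half_life_s,
         lines = lines,
         beta_branches = beta_branches,
         local_energy_sub1kev = local_energy_sub1kev,
         n_sub1kev_ae = n_sub1kev_ae),
    class = "nr_spectrum"
  )
}

#' @export
print.nr_spectrum <- function(x, ...) {
  cat("<nr_spectrum>", x$nuclide_id, "\n")
  cat("  lines >= 1 keV:", nrow(x$lines),
      " beta branches:", nrow(x$beta_branches), "\n")
  cat(sprintf("  sub-1-keV AE: %.4g keV/decay (%.3g electrons)\n",
              x$local_energy_sub1kev, x$n_sub1kev_ae))
  cat(sprintf("  mean electron energy per decay: %.4g keV\n",
              mean_energy_per_decay(x)))
  invisible(x)
}

#' Total Auger/Coster-Kronig electron yield per decay
#'
#' Counts grouped AE lines at or above 1 keV plus the expected number of
#' sub-1-keV AE whose energy is deposited locally.
#'
#' @param spectrum An `nr_spectrum`.
#' @return Expected AE count per decay.
#' @export
total_ae_yield <- function(spectrum) {
  stopifnot(inherits(spectrum, "nr_spectrum"))
  ae <- spectrum$lines$kind == "AE"
  sum(spectrum$lines$yield[ae]) + spectrum$n_sub1kev_ae
}

#' Mean electron energy per decay
#'
#' Expected energy (keV) carried by all non-radiative emissions of one decay:
#' line energies weighted by yield, beta branch mean energies weighted by
#' branch yield, plus the locally deposited sub-1-keV AE energy.
#'
#' @param spectrum An `nr_spectrum`.
#' @return Mean energy in keV per decay.
#' @export
mean_energy_per_decay <- function(spectrum) {
  stopifnot(inherits(spectrum, "nr_spectrum"))
  e <- sum(spectrum$lines$energy_keV * spectrum$lines$yield)
  bb <- spectrum$beta_branches
  if (nrow(bb)) {
    for (i in seq_len(nrow(bb))) {
      e <- e + bb$yield[i] * beta_mean_energy(bb$endpoint_keV[i], bb$daughter_Z[i])
    }
  }
  e + spectrum$local_energy_sub1kev
}

#' Define a synthetic nuclide for validation
#'
#' Builds an `nr_spectrum` from explicit components. Toy nuclides are used as
#' analytic oracles: monoenergetic emitters make absorbed fractions and S
#' values computable in closed form. With `register = TRUE` (default when an
#' id is supplied) the nuclide becomes loadable through [load_spectrum()].
#'
#' @param lines Data frame with columns `kind` (`"AE"`/`"CE"`), `energy_keV`
#'   (>= 1), `yield`; or `NULL` for none.
#' @param beta_branches Data frame with columns `endpoint_keV`, `yield`
#'   (and optionally `shape`, `daughter_Z`); or `NULL` for none.
#' @param local_energy Sub-1-keV energy (keV) deposited at the decay site.
#' @param nuclide_id Identifier; defaults to `"toy"`.
#' @param register Register in the session toy-nuclide registry.
#' @return An `nr_spectrum`.
#' @examples
#' toy <- make_toy_nuclide(lines = data.frame(kind = "CE", energy_keV = 20, yield = 1))
#' mean_energy_per_decay(toy)  # 20
#' @export
make_toy_nuclide <- function(lines = NULL, beta_branches = NULL,
                             local_energy = 0, nuclide_id = "toy",
                             register = TRUE) {
  if (is.null(lines)) {
    lines <- data.frame(kind = character(0), energy_keV = numeric(0),
                        yield = numeric(0), stringsAsFactors = FALSE)
  }
  if (is.null(beta_branches)) {
    beta_branches <- data.frame(endpoint_keV = numeric(0), yield = numeric(0),
                                shape = character(0), daughter_Z = integer(0),
                                stringsAsFactors = FALSE)
  } else {
    if (is.null(beta_branches$shape)) beta_branches$shape <- "allowed"
    if (is.null(beta_branches$daughter_Z)) beta_branches$daughter_Z <- 54L
  }
  sp <- new_nr_spectrum(nuclide_id, lines, beta_branches,
                        local_energy_sub1kev = local_energy)
  if (register) {
    reg <- toy_registry()
    reg[[nuclide_id]] <- sp
    .thyrodose_env$toys <- reg
  }
  sp
}

toy_registry <- function() {
  reg <- .thyrodose_env$toys
  if (is.null(reg)) list() else reg
}

#' Sample the emissions of decays
#'
#' Draws per-decay emission sets from a spectrum: each grouped line's emission
#' count is Poisson with mean equal to its yield (the conventional,
#' uncorrelated AE spectrum), a beta branch is selected by branch yield with
#' its energy drawn from the allowed spectral shape, and directions are
#' isotropic and independent. Sub-1-keV AE energy appears as `local_deposit`.
#' Uses R's global random number stream; seed with [set.seed()].
#'
#' @param spectrum An `nr_spectrum`.
#' @param n Number of decays to sample.
#' @return A list with `electrons` (data frame `decay`, `kind`, `energy_keV`,
#'   `ux`, `uy`, `uz`) and `local_deposit` (keV, common to every decay).
#' @export
sample_decay_emissions <- function(spectrum, n = 1L) {
  em <- sample_emissions_flat(spectrum, n)
  nd <- length(em$energy)
  if (nd) {
    u <- isotropic_directions(nd)
    electrons <- data.frame(decay = em$decay, kind = em$kind_chr,
                            energy_keV = em$energy,
                            ux = u[, 1], uy = u[, 2], uz = u[, 3])
  } else {
    electrons <- data.frame(decay = integer(0), kind = character(0),
                            energy_keV = numeric(0), ux = numeric(0),
                            uy = numeric(0), uz = numeric(0))
  }
  list(electrons = electrons, local_deposit = spectrum$local_energy_sub1kev)
}

# Flat emission sampler used by the engines: no directions, integer kinds
# (0 = AE, 1 = CE, 2 = beta). Returns parallel vectors decay/energy/kind.
sample_emissions_flat <- function(spectrum, n) {
  decay <- integer(0)
  energy <- numeric(0)
  kind <- integer(0)
  ln <- spectrum$lines
  for (i in seq_len(nrow(ln))) {
    cnt <- rpois(n, ln$yield[i])
    idx <- rep.int(seq_len(n), cnt)
    if (length(idx)) {
      decay <- c(decay, idx)
      energy <- c(energy, rep.int(ln$energy_keV[i], length(idx)))
      kind <- c(kind, rep.int(if (ln$kind[i] == "AE") 0L else 1L, length(idx)))
    }
  }
  bb <- spectrum$beta_branches
  if (nrow(bb)) {
    ytot <- sum(bb$yield)
    emit <- runif(n) < min(ytot, 1)
    idx <- which(emit)
    if (length(idx)) {
      br <- sample.int(nrow(bb), length(idx), replace = TRUE,
                       prob = bb$yield / ytot)
      eb <- numeric(length(idx))
      for (b in unique(br)) {
        sel <- br == b
        eb[sel] <- sample_beta_energy(sum(sel), bb$endpoint_keV[b],
                                      bb$daughter_Z[b])
      }
      decay <- c(decay, idx)
      energy <- c(energy, eb)
      kind <- c(kind, rep.int(2L, length(idx)))
    }
  }
  list(decay = decay, energy = energy, kind = kind,
       kind_chr = c("AE", "CE", "beta")[kind + 1L])
}

isotropic_directions <- function(n) {
  cz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  st <- sqrt(pmax(0, 1 - cz^2))
  cbind(st * cos(phi), st * sin(phi), cz)
}
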