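# Shared test helpers: independent oracles and small fixture builders.

default_grid <- age_grid()

# Build a life table directly from a q vector on the default grid.
table_from_q <- function(q, radix = 1e5, rules = a_rules()) {
  life_table(tibble::tibble(age_start = default_grid$age_start,
                            age_span = default_grid$age_span,
                            qx = q),
             radix = radix, rules = rules)
}

# A plausible random abridged schedule: baseline shifted by a random level
# plus independent logit noise per group.
random_schedule_q <- function(level_sd = 1, noise_sd = 0.15) {
  eta <- baseline_logit_schedule(stats::rnorm(1, 0, level_sd)) +
    stats::rnorm(sum(default_grid$age_span > 0), 0, noise_sd)
  c(1 / (1 + exp(-eta)), 1)
}

# Fine-grid numerical life table: deaths spread piecewise-uniformly on a
# 0.01-year grid (open-group deaths uniform on [start, start + 2 * a_open]).
# Independent of the package's point-mass/a-value conventions.
fine_oracle <- function(q, step = 0.01, a_open = 2.5) {
  starts <- default_grid$age_start
  spans <- default_grid$age_span
  n <- length(q)
  q[n] <- 1
  l <- cumprod(c(1, 1 - q[-n]))
  d <- l * q
  spans[n] <- 2 * a_open
  m <- round(spans / step)
  z <- unlist(lapply(seq_len(n), function(i) {
    starts[i] + (seq_len(m[i]) - 0.5) * step
  }))
  w <- unlist(lapply(seq_len(n), function(i) rep(d[i] / m[i], m[i])))
  grp <- rep(seq_len(n), m)

  cond <- function(x) {
    keep <- z >= x
    list(z = z[keep], w = w[keep] / sum(w[keep]))
  }
  e_at <- function(x) { c <- cond(x); sum(c$w * (c$z - x)) }
  sd_at <- function(x) {
    c <- cond(x); mu <- sum(c$w * c$z); sqrt(sum(c$w * (c$z - mu)^2))
  }
  gini_at <- function(x) { # Lorenz trapezoid on the fine masses
    c <- cond(x)
    o <- order(c$z); zz <- c$z[o]; ww <- c$w[o]
    Fc <- cumsum(ww); Lc <- cumsum(ww * zz) / sum(ww * zz)
    1 - sum(diff(c(0, Fc)) * (Lc + c(0, utils::head(Lc, -1))))
  }
  pct_at <- function(p, x) {
    keep <- z >= x
    ww <- w[keep]
    i <- which(cumsum(ww) >= p * sum(ww))[1]
    z[keep][i]
  }
  modal_group <- function() which.max(tapply(w, grp, sum))
  list(
    e0 = e_at(0), e65 = e_at(65), s0 = sd_at(0), s65 = sd_at(65),
    G0 = gini_at(0), G65 = gini_at(65),
    y50_0 = pct_at(0.5, 0), y75_65 = pct_at(0.75, 65),
    modal_group = modal_group()
  )
}

# The package places deaths at a point mass (start + ax) within each group,
# while the fine-grid oracle spreads them uniformly. The gap between the two
# conventions is known in closed form: uniform spread adds span^2/12 to the
# variance and span/3 to same-group pairwise absolute differences. These
# terms let the oracle comparison test distributional agreement beyond the
# documented convention difference.
pointmass_correction <- function(lt, age) {
  dd <- death_ages(lt, age)
  spans <- lt$age_span[lt$age_start >= age]
  spans[spans < 0] <- 2 * lt$ax[nrow(lt)]
  list(var_add = sum(dd$weight * spans^2 / 12),
       mad_add = sum(dd$weight^2 * spans / 3),
       mu = sum(dd$weight * dd$age))
}

# Lorenz-curve trapezoid Gini on a discrete death-age distribution --
# an independent route to the package's pairwise double sum.
gini_lorenz <- function(age, weight) {
  w <- weight / sum(weight)
  o <- order(age)
  z <- age[o]; w <- w[o]
  Fc <- cumsum(w)
  Lc <- cumsum(w * z) / sum(w * z)
  1 - sum(diff(c(0, Fc)) * (Lc + c(0, utils::head(Lc, -1))))
}

# All assignments of n items to exactly k non-empty unlabelled groups
# (canonical labelling: label j first appears after labels 1..j-1).
all_partitions <- function(n, k) {
  out <- list()
  rec <- function(assign, used) {
    i <- length(assign) + 1
    if (i > n) {
      if (used == k) out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(min(used + 1, k))) rec(c(assign, lab), max(used, lab))
  }
  rec(integer(0), 0L)
  out
}

partition_wss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(ix) {
    xm <- x[ix, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }, numeric(1)))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Wrap a bare country x indicator matrix as an indicator_panel tibble.
as_indicator_panel <- function(values, sex = "female", period_start = 1990) {
  stopifnot(ncol(values) == 9)
  colnames(values) <- c("e0", "e65", "M", "G0", "G65", "s0", "s65",
                        "y50_0", "y75_65")
  out <- tibble::tibble(
    country = sprintf("c%03d", seq_len(nrow(values))),
    code = sprintf("c%03d", seq_len(nrow(values))),
    sex = sex, period_start = period_start
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  class(out) <- c("indicator_panel", class(out))
  out
}
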