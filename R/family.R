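# Model families for APC count surfaces.  The linear predictor eta is the
# log *rate*; for count families the offset log(population) converts it to
# the log mean.  Gaussian (identity link, no offset) is provided for
# theoretical checks and Gaussian-data use.

apc_family <- function(name = c("poisson", "negative_binomial", "gaussian"),
                       theta = NULL) {
  name <- match.arg(name)
  if (name == "negative_binomial" && !is.null(theta) && theta <= 0) {
    abort("Negative-binomial dispersion `theta` must be positive.")
  }
  if (name == "gaussian") theta <- theta %||% 1 # residual sd
  structure(list(name = name, theta = theta), class = "apc_family")
}

family_offset <- function(family, population) {
  if (family$name == "gaussian") rep(0, length(population)) else log(population)
}

family_mu <- function(family, eta, off) {
  # cap the log mean to keep extreme proposals finite rather than fatal
  if (family$name == "gaussian") eta else exp(pmin(eta + off, 300))
}

family_loglik <- function(family, y, eta, off) {
  mu <- family_mu(family, eta, off)
  switch(family$name,
    poisson = sum(dpois(y, mu, log = TRUE)),
    negative_binomial = sum(dnbinom(y, size = family$theta, mu = mu, log = TRUE)),
    gaussian = sum(dnorm(y, mu, family$theta, log = TRUE))
  )
}

# IRLS working weights and response at the current eta.
family_irls <- function(family, y, eta, off) {
  if (family$name == "gaussian") {
    return(list(w = rep(1 / family$theta^2, length(y)), z = y))
  }
  mu <- pmax(family_mu(family, eta, off), 1e-300)
  w <- if (family$name == "poisson") mu else mu / (1 + mu / family$theta)
  list(w = w, z = eta + (y - mu) / mu)
}

family_deviance <- function(family, y, eta, off) {
  mu <- family_mu(family, eta, off)
  switch(family$name,
    poisson = {
      term <- ifelse(y > 0, y * log(y / mu), 0)
      2 * sum(term - (y - mu))
    },
    negative_binomial = {
      th <- family$theta
      term <- ifelse(y > 0, y * log(y / mu), 0)
      2 * sum(term - (y + th) * log((y + th) / (mu + th)))
    },
    gaussian = sum((y - mu)^2) / family$theta^2
  )
}

# First derivative of the log-likelihood wrt eta, and its negative second
# derivative (Fisher weights at the observed information for the families
# used; canonical-link Poisson makes these exact).
family_grad_hess <- function(family, y, eta, off) {
  if (family$name == "gaussian") {
    return(list(g = (y - eta) / family$theta^2,
                h = rep(1 / family$theta^2, length(y))))
  }
  mu <- family_mu(family, eta, off)
  if (family$name == "poisson") {
    list(g = y - mu, h = mu)
  } else {
    th <- family$theta
    list(
      g = y - (y + th) * mu / (mu + th),
      h = (y + th) * mu * th / (mu + th)^2
    )
  }
}
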