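# The JAGS "glm" module provides blocked samplers for generalized linear
# mixed models; without it, group intercepts and day effects (jointly
# weakly identified with few days) mix an order of magnitude more slowly.
.onLoad <- function(libname, pkgname) {
  tryCatch(rjags::load.module("glm", quiet = TRUE), error = function(e) NULL)
}
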