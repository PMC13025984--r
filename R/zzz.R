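.onLoad <- function(libname, pkgname) {
  register_codec("gzip", function(x) memCompress(x, type = "gzip"))
  register_codec("bzip2", function(x) memCompress(x, type = "bzip2"))
  register_codec("xz", function(x) memCompress(x, type = "xz"))
  invisible()
}
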