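# Loopback HTTP range server used to exercise remote byte sources without a
# network. Backed by the bundled Python script (Python 3 on PATH).

#' Start a loopback HTTP server with Range support
#'
#' Serves `root` on 127.0.0.1 at an OS-assigned port. With `honor_range =
#' FALSE` the server deliberately ignores `Range` headers, which lets the
#' whole-file fallback of [open_byte_source()] be exercised.
#'
#' @param root directory to serve.
#' @param honor_range serve 206 partial responses (default `TRUE`).
#' @param timeout seconds to wait for the server to come up.
#' @return list with `url` (base URL), `port`, `pid`; pass to
#'   [stop_range_server()].
#' @export
start_range_server <- function(root, honor_range = TRUE, timeout = 10) {
  script <- system.file("rangeserver", "range_server.py",
                        package = "spattile")
  stopifnot(nzchar(script), dir.exists(root))
  log <- tempfile("rangeserver", fileext = ".log")
  cmd <- sprintf("python '%s' 0 '%s'%s > '%s' 2>&1 & echo $!",
                 script, normalizePath(root),
                 if (honor_range) "" else " --no-range", log)
  pid <- as.integer(system(cmd, intern = TRUE))
  t0 <- Sys.time()
  port <- NA_integer_
  while (as.numeric(Sys.time() - t0) < timeout) {
    if (file.exists(log)) {
      ln <- readLines(log, warn = FALSE)
      m <- grep("^READY ", ln, value = TRUE)
      if (length(m) > 0L) {
        port <- as.integer(sub("^READY ", "", m[1]))
        break
      }
    }
    Sys.sleep(0.05)
  }
  if (is.na(port)) {
    tools::pskill(pid)
    stop("range server failed to start; log:\n",
         paste(readLines(log, warn = FALSE), collapse = "\n"))
  }
  list(url = sprintf("http://127.0.0.1:%d", port), port = port, pid = pid)
}

#' Stop a loopback range server
#' @param server value returned by [start_range_server()].
#' @export
stop_range_server <- function(server) {
  if (!is.null(server$pid)) tools::pskill(server$pid)
  invisible(NULL)
}
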