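"""Minimal static file server with HTTP Range support, for exercising
byte-range (lazy) reads against a loopback URL.

Usage: python range_server.py PORT ROOT_DIR [--no-range]
Prints "READY <port>" on stdout once listening. --no-range makes it ignore
Range headers (always 200 + full body), to exercise the client fallback.
"""
import http.server
import os
import re
import sys


class RangeHandler(http.server.SimpleHTTPRequestHandler):
    honor_range = True

    def log_message(self, *args):
        pass

    def do_GET(self):
        path = self.translate_path(self.path)
        if not os.path.isfile(path):
            self.send_error(404)
            return
        with open(path, "rb") as fh:
            data = fh.read()
        rng = self.headers.get("Range")
        m = re.match(r"bytes=(\d+)-(\d*)$", rng or "")
        if m and self.honor_range:
            start = int(m.group(1))
            end = int(m.group(2)) if m.group(2) else len(data) - 1
            end = min(end, len(data) - 1)
            chunk = data[start:end + 1]
            self.send_response(206)
            self.send_header("Content-Range",
                             "bytes %d-%d/%d" % (start, end, len(data)))
        else:
            chunk = data
            self.send_response(200)
        self.send_header("Accept-Ranges",
                         "bytes" if self.honor_range else "none")
        self.send_header("Content-Length", str(len(chunk)))
        self.end_headers()
        self.wfile.write(chunk)


def main():
    port = int(sys.argv[1])
    root = sys.argv[2]
    RangeHandler.honor_range = "--no-range" not in sys.argv[3:]
    os.chdir(root)
    srv = http.server.ThreadingHTTPServer(("127.0.0.1", port), RangeHandler)
    sys.stdout.write("READY %d\n" % srv.server_address[1])
    sys.stdout.flush()
    srv.serve_forever()


if __name__ == "__main__":
    main()
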