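#include <Rcpp.h>

#include <sys/types.h>
#include <sys/wait.h>
#include <sys/resource.h>
#include <sys/time.h>
#include <unistd.h>
#include <cerrno>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Run `cmd args...` as a child process and report wall time, exit status and
// the child's peak resident set size (via wait4 rusage).  POSIX only; this is
// the benchmarking protocol, not part of the codec path.

// [[Rcpp::export]]
List run_measured_(std::string cmd, CharacterVector args) {
    std::vector<std::string> sargs;
    sargs.push_back(cmd);
    for (int i = 0; i < args.size(); ++i)
        sargs.push_back(as<std::string>(args[i]));
    std::vector<char*> argv;
    for (auto& s : sargs) argv.push_back(const_cast<char*>(s.c_str()));
    argv.push_back(nullptr);

    struct timeval t0, t1;
    gettimeofday(&t0, nullptr);

    pid_t pid = fork();
    if (pid < 0) stop("fork failed: %s", strerror(errno));
    if (pid == 0) {
        execvp(cmd.c_str(), argv.data());
        _exit(127);  // exec failed
    }

    int status = 0;
    struct rusage ru;
    memset(&ru, 0, sizeof(ru));
    if (wait4(pid, &status, 0, &ru) < 0)
        stop("wait4 failed: %s", strerror(errno));
    gettimeofday(&t1, nullptr);

    double elapsed = (t1.tv_sec - t0.tv_sec) + (t1.tv_usec - t0.tv_usec) / 1e6;
    int exit_code = WIFEXITED(status) ? WEXITSTATUS(status) : -1;
    double max_rss_mb = ru.ru_maxrss / 1024.0;  // Linux reports KiB

    return List::create(
        _["exit_code"] = exit_code,
        _["elapsed"] = elapsed,
        _["max_rss_mb"] = max_rss_mb);
}
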