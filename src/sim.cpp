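#include <Rcpp.h>
using namespace Rcpp;

// Event-driven-in-spirit fixed-step integrator for the nIC-1EC network.
// Between spikes every gating variable (Ca, si, se) obeys a linear ODE and
// is advanced by its exact exponential factor; the membrane potential is
// advanced by exponential Euler with conductances frozen at the step start
// (the voltage equation is linear in v given the gates). Threshold checks
// happen at step end; the spike time is the step end.
//
// Neuron ids in the returned spike train: 0 = EC, 1..nIC = inhibitory cells.
//
// If two ICs cross threshold in the same step, the one with the lower
// calcium (the more excitable one) fires; ties go to the lower index. The
// loser is not reset: the winner's freshly reset inhibition pulls it back
// below threshold on the following step.

// [[Rcpp::export]]
List sim_network_cpp(NumericVector par, int nIC, NumericVector ca0,
                     NumericVector v0, double vEC0, double tmax, double dt,
                     int record_every, int max_interchanges, bool has_ec) {
  const double Cm = par["Cm"], gl = par["gl"], EL = par["EL"],
               vT = par["vT"], vR = par["vR"], gAHP = par["gAHP"],
               k1 = par["k1"], EK = par["EK"], kCa = par["kCa"],
               dCa = par["dCa"], Iapp = par["Iapp"], Istim = par["Istim"],
               gi = par["gi"], ge = par["ge"], EGABA = par["EGABA"],
               EAMPA = par["EAMPA"], betai = par["betai"],
               betae = par["betae"];

  const int nsteps = (int)std::ceil(tmax / dt);
  const double fCa = std::exp(-kCa * dt);
  const double fsi = std::exp(-betai * dt);
  const double fse = std::exp(-betae * dt);
  const double fEC = std::exp(-gl * dt / Cm);
  const double vinfEC = EL + Istim / gl;

  std::vector<double> v(v0.begin(), v0.end());   // length nIC
  std::vector<double> Ca(ca0.begin(), ca0.end());
  std::vector<double> si(nIC, 0.0);
  double se = 0.0, vEC = vEC0;

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  std::vector<double> sp_ca;  // row-major nIC-wide snapshots at IC spikes

  const bool rec = record_every > 0;
  std::vector<double> tr;
  int ntr = 0;
  if (rec) tr.reserve((nsteps / record_every + 2) * (2 + 3 * nIC + 2));

  int last_active = -1, interchanges = 0;
  bool done = false;

  for (int step = 0; step < nsteps && !done; ++step) {
    const double t = (step + 1) * dt;

    // exact decay of the slow/gating variables
    for (int j = 0; j < nIC; ++j) { Ca[j] *= fCa; si[j] *= fsi; }
    se *= fse;

    // membrane potentials: exponential Euler, coefficients at step start
    for (int j = 0; j < nIC; ++j) {
      double S = 0.0;
      for (int k = 0; k < nIC; ++k) if (k != j) S += si[k];
      const double xCa = Ca[j] / (Ca[j] + k1);
      const double gtot = gl + gAHP * xCa + gi * S + ge * se;
      const double vinf = (gl * EL + gAHP * xCa * EK + gi * S * EGABA +
                           ge * se * EAMPA + Iapp) / gtot;
      v[j] = vinf + (v[j] - vinf) * std::exp(-gtot * dt / Cm);
    }
    if (has_ec) {
      vEC = vinfEC + (vEC - vinfEC) * fEC;
      // EC threshold: reset and re-open the excitatory gate
      if (vEC >= vT) {
        sp_t.push_back(t); sp_id.push_back(0);
        vEC = vR; se = 1.0;
      }
    }

    // IC threshold: at most one IC fires per step (lowest calcium wins)
    int winner = -1;
    for (int j = 0; j < nIC; ++j) {
      if (v[j] >= vT && (winner < 0 || Ca[j] < Ca[winner])) winner = j;
    }
    if (winner >= 0) {
      sp_t.push_back(t); sp_id.push_back(winner + 1);
      for (int k = 0; k < nIC; ++k) sp_ca.push_back(Ca[k]);  // pre-jump
      Ca[winner] += dCa;
      v[winner] = vR;
      si[winner] = 1.0;
      if (winner != last_active) {
        if (last_active >= 0) {
          ++interchanges;
          if (max_interchanges > 0 && interchanges >= max_interchanges)
            done = true;
        }
        last_active = winner;
      }
    }

    if (rec && (step % record_every == 0)) {
      tr.push_back(t);
      for (int j = 0; j < nIC; ++j) tr.push_back(v[j]);
      tr.push_back(vEC);
      for (int j = 0; j < nIC; ++j) tr.push_back(Ca[j]);
      for (int j = 0; j < nIC; ++j) tr.push_back(si[j]);
      tr.push_back(se);
      ++ntr;
    }

    if ((step & 1023) == 0) {
      bool ok = std::isfinite(vEC);
      for (int j = 0; j < nIC && ok; ++j)
        ok = std::isfinite(v[j]) && std::isfinite(Ca[j]);
      if (!ok) stop("non-finite network state at t = %f ms", t);
    }
  }

  const int nsp = (int)sp_t.size();
  int nIC_sp = 0;
  for (int i = 0; i < nsp; ++i) if (sp_id[i] > 0) ++nIC_sp;
  NumericMatrix spCa(nIC_sp, std::max(nIC, 1));
  {
    int rI = 0;
    for (int i = 0; i < nsp; ++i) {
      if (sp_id[i] > 0) {
        for (int k = 0; k < nIC; ++k) spCa(rI, k) = sp_ca[(size_t)rI * nIC + k];
        ++rI;
      }
    }
  }

  NumericMatrix trace(ntr, rec ? 2 + 3 * nIC + 1 : 0);
  if (rec) {
    const int w = 2 + 3 * nIC + 1;
    for (int i = 0; i < ntr; ++i)
      for (int c = 0; c < w; ++c) trace(i, c) = tr[(size_t)i * w + c];
  }

  return List::create(_["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
                      _["spike_ca"] = spCa,
                      _["trace"] = trace);
}
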