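#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Discrete-time GLIF3 network integrator.
//
// State convention: all state vectors hold values at time step t (t in
// 0..T-1, physical time t*dt). One iteration advances t -> t+1 as:
//   1. record state at t (traces / window sums),
//   2. threshold test z(t) = H(v(t) - vth) outside refractoriness; a spike
//      schedules weighted arrivals into delay buffers at t + delay,
//   3. membrane / after-spike-current update using currents at t,
//   4. alpha-synapse update consuming the arrivals due at t:
//        I(t+1) = a*(I(t) + dt*C(t));  C(t+1) = a*C(t) + arr(t)*e/tau
//      with a = exp(-dt/tau).
// Synaptic channels per neuron: 0 = LGN ("in"), 1 = background ("noise"),
// 2 = recurrent from excitatory, 3 = recurrent from inhibitory; the
// recurrent source current is channel 2 + channel 3.
//
// Refractoriness: a spike at t sets v = vr and a countdown of refSteps;
// integration of v is suspended while the countdown runs (synapses and
// after-spike currents keep evolving, the latter by pure decay) and the
// after-spike reset I_m <- R_m*I_m + A_m is applied once, when the
// countdown expires.

// [[Rcpp::export]]
List cpp_glif_trial(NumericVector v, NumericVector asc1, NumericVector asc2,
                    IntegerVector refr,
                    NumericMatrix synI, NumericMatrix synC, // 4 x N
                    NumericVector alphaMem, NumericVector gmem,
                    NumericVector EL, NumericVector vth, NumericVector vr,
                    IntegerVector refSteps,
                    NumericVector dk1, NumericVector dk2, // exp(-k_m*dt)
                    NumericVector A1, NumericVector A2,
                    NumericVector R1, NumericVector R2,
                    NumericMatrix chanDecay, NumericMatrix chanTau, // 4 x N
                    IntegerVector recPtr, IntegerVector recPost,
                    IntegerVector recDelay, IntegerVector recChan,
                    NumericVector recW,
                    IntegerVector lgnPtr, IntegerVector lgnPost,
                    IntegerVector lgnDelay, NumericVector lgnW,
                    NumericVector bkgW,
                    IntegerMatrix lgnCounts,   // nUnits x T (may be 0 x T)
                    IntegerVector bkgCounts,   // length T
                    NumericVector iInject,     // constant extra current, pA
                    int T, double dt,
                    IntegerVector winStart, IntegerVector winEnd,
                    bool recordTraces) {
  const int N = v.size();
  const int nUnits = lgnCounts.nrow();
  const int nWin = winStart.size();

  int maxDelay = 1;
  for (int s = 0; s < recDelay.size(); ++s)
    if (recDelay[s] > maxDelay) maxDelay = recDelay[s];
  for (int s = 0; s < lgnDelay.size(); ++s)
    if (lgnDelay[s] > maxDelay) maxDelay = lgnDelay[s];
  const int D = maxDelay + 2;

  // delay buffers: buf[((slot*4)+ch)*N + j]
  std::vector<double> buf((size_t)D * 4 * N, 0.0);

  // window sums: [win][src][neuron], src 0..3 = in, noise, rec, asc
  std::vector<double> wsum((size_t)nWin * 4 * N, 0.0);

  NumericMatrix trIn, trNoise, trRec, trAsc, trV;
  if (recordTraces) {
    trIn = NumericMatrix(T, N);
    trNoise = NumericMatrix(T, N);
    trRec = NumericMatrix(T, N);
    trAsc = NumericMatrix(T, N);
    trV = NumericMatrix(T, N);
  }

  std::vector<int> spkNeuron, spkStep;
  const double e1 = std::exp(1.0);

  for (int t = 0; t < T; ++t) {
    // 1. record state at time t
    if (recordTraces) {
      for (int j = 0; j < N; ++j) {
        trIn(t, j) = synI(0, j);
        trNoise(t, j) = synI(1, j);
        trRec(t, j) = synI(2, j) + synI(3, j);
        trAsc(t, j) = asc1[j] + asc2[j];
        trV(t, j) = v[j];
      }
    }
    for (int w = 0; w < nWin; ++w) {
      if (t >= winStart[w] && t < winEnd[w]) {
        double *base = &wsum[(size_t)w * 4 * N];
        for (int j = 0; j < N; ++j) {
          base[j] += synI(0, j);
          base[N + j] += synI(1, j);
          base[2 * N + j] += synI(2, j) + synI(3, j);
          base[3 * N + j] += asc1[j] + asc2[j];
        }
      }
    }

    // 2a. threshold test at time t
    for (int j = 0; j < N; ++j) {
      if (refr[j] == 0 && v[j] >= vth[j]) {
        spkNeuron.push_back(j);
        spkStep.push_back(t);
        refr[j] = refSteps[j];
        v[j] = vr[j];
        for (int s = recPtr[j]; s < recPtr[j + 1]; ++s) {
          int slot = (t + recDelay[s]) % D;
          buf[((size_t)slot * 4 + recChan[s]) * N + recPost[s]] += recW[s];
        }
      }
    }

    // 2b. external spike sources at time t
    for (int u = 0; u < nUnits; ++u) {
      int c = lgnCounts(u, t);
      if (c > 0) {
        for (int s = lgnPtr[u]; s < lgnPtr[u + 1]; ++s) {
          int slot = (t + lgnDelay[s]) % D;
          buf[((size_t)slot * 4 + 0) * N + lgnPost[s]] += c * lgnW[s];
        }
      }
    }
    if (bkgCounts[t] > 0) {
      int slot = (t + 1) % D;
      double c = (double)bkgCounts[t];
      for (int j = 0; j < N; ++j)
        buf[((size_t)slot * 4 + 1) * N + j] += c * bkgW[j];
    }

    // 3. membrane and after-spike currents (use currents at time t)
    for (int j = 0; j < N; ++j) {
      double a1n = dk1[j] * asc1[j];
      double a2n = dk2[j] * asc2[j];
      if (refr[j] > 0) {
        refr[j] -= 1;
        if (refr[j] == 0) { // refractory release: Eq-3 reset
          a1n = R1[j] * a1n + A1[j];
          a2n = R2[j] * a2n + A2[j];
        }
        // v held at vr during the refractory period
      } else {
        double Iext = synI(0, j) + synI(1, j) + synI(2, j) + synI(3, j) +
                      iInject[j];
        double Iint = asc1[j] + asc2[j];
        v[j] = alphaMem[j] * v[j] +
               (1.0 - alphaMem[j]) * ((Iext + Iint) / gmem[j] + EL[j]);
      }
      asc1[j] = a1n;
      asc2[j] = a2n;
    }

    // 4. alpha-synapse update consuming arrivals due at t
    int slot = t % D;
    for (int ch = 0; ch < 4; ++ch) {
      double *arr = &buf[((size_t)slot * 4 + ch) * N];
      for (int j = 0; j < N; ++j) {
        double a = chanDecay(ch, j);
        double I = synI(ch, j), Cc = synC(ch, j);
        synI(ch, j) = a * (I + dt * Cc);
        synC(ch, j) = a * Cc + arr[j] * e1 / chanTau(ch, j);
        arr[j] = 0.0;
      }
    }
  }

  // package window sums as list of nWin x N matrices per source
  List wlist(4);
  for (int s = 0; s < 4; ++s) {
    NumericMatrix m(nWin, N);
    for (int w = 0; w < nWin; ++w)
      for (int j = 0; j < N; ++j)
        m(w, j) = wsum[((size_t)w * 4 + s) * N + j];
    wlist[s] = m;
  }
  wlist.names() = CharacterVector::create("in", "noise", "rec", "asc");

  List out = List::create(
      _["spikeNeuron"] = wrap(spkNeuron), _["spikeStep"] = wrap(spkStep),
      _["windowSums"] = wlist);
  if (recordTraces) {
    out["traces"] = List::create(_["in"] = trIn, _["noise"] = trNoise,
                                 _["rec"] = trRec, _["asc"] = trAsc,
                                 _["v"] = trV);
  }
  return out;
}

// Rheobase search: rectangular pulses from rest (v = EL, after-spike
// currents zero), starting at `start` pA and incrementing by `inc` pA,
// until a pulse of `pulseSteps` steps elicits a spike. State is reset
// between pulses (the resting interval). Returns the first firing grid
// current, or NA if `ceiling` is reached.
// [[Rcpp::export]]
double cpp_rheobase(double Cap, double g, double EL, double vth, double dt,
                    double start, double inc, double ceiling,
                    int pulseSteps) {
  double tau = Cap / g;
  double alpha = std::exp(-dt / tau);
  for (double I = start; I <= ceiling + 1e-12; I += inc) {
    double vv = EL;
    bool fired = (vv >= vth);
    for (int t = 0; t < pulseSteps && !fired; ++t) {
      vv = alpha * vv + (1.0 - alpha) * (I / g + EL);
      if (vv >= vth) fired = true;
    }
    if (fired) return I;
  }
  return NA_REAL;
}
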