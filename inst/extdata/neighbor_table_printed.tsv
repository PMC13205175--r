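invariant_label	side	neighbor_label
C3	five_prime	G2
G6	five_prime	C5
A9	five_prime	C8
T13	five_prime	C12
T18	five_prime	C17
C26	five_prime	G25
T34	five_prime	G33
A10	three_prime	C11
G22	three_prime	T23
G15	three_prime	C16
C20	three_prime	G21
C28	three_prime	G29
A31	three_prime	G32
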