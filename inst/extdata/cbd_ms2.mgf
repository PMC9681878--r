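BEGIN IONS
TITLE=CBD_RT4.99
PEPMASS=315.231900
COLLISION_ENERGY=25-50 eV
135.116900 25.000000
193.122800 100.000000
259.169300 35.000000
END IONS

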