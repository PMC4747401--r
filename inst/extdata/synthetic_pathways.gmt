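nucleotide_metabolism	synthetic pathway fixture	g00001	g00002	g00003	g00004	g00005	g00006	g00007	g00008
dna_repair	synthetic pathway fixture	g00009	g00010	g00011	g00012	g00013	g00014
drug_transport	synthetic pathway fixture	g00015	g00016	g00017	g00018	g00019	g00020	g00021
glycolysis	synthetic pathway fixture	g00022	g00023	g00024	g00025	g00026	g00027	g00028	g00029	g00030
apoptosis_signaling	synthetic pathway fixture	g00031	g00032	g00033	g00034	g00035	g00036	g00037	g00038	g00039	g00040
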