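G1S	synthetic G1/S core set (43 genes)	G1S.SYN.01	G1S.SYN.02	G1S.SYN.03	G1S.SYN.04	G1S.SYN.05	G1S.SYN.06	G1S.SYN.07	G1S.SYN.08	G1S.SYN.09	G1S.SYN.10	G1S.SYN.11	G1S.SYN.12	G1S.SYN.13	G1S.SYN.14	G1S.SYN.15	G1S.SYN.16	G1S.SYN.17	G1S.SYN.18	G1S.SYN.19	G1S.SYN.20	G1S.SYN.21	G1S.SYN.22	G1S.SYN.23	G1S.SYN.24	G1S.SYN.25	G1S.SYN.26	G1S.SYN.27	G1S.SYN.28	G1S.SYN.29	G1S.SYN.30	G1S.SYN.31	G1S.SYN.32	G1S.SYN.33	G1S.SYN.34	G1S.SYN.35	G1S.SYN.36	G1S.SYN.37	G1S.SYN.38	G1S.SYN.39	G1S.SYN.40	G1S.SYN.41	G1S.SYN.42	G1S.SYN.43
G2M	synthetic G2/M core set (54 genes)	G2M.SYN.01	G2M.SYN.02	G2M.SYN.03	G2M.SYN.04	G2M.SYN.05	G2M.SYN.06	G2M.SYN.07	G2M.SYN.08	G2M.SYN.09	G2M.SYN.10	G2M.SYN.11	G2M.SYN.12	G2M.SYN.13	G2M.SYN.14	G2M.SYN.15	G2M.SYN.16	G2M.SYN.17	G2M.SYN.18	G2M.SYN.19	G2M.SYN.20	G2M.SYN.21	G2M.SYN.22	G2M.SYN.23	G2M.SYN.24	G2M.SYN.25	G2M.SYN.26	G2M.SYN.27	G2M.SYN.28	G2M.SYN.29	G2M.SYN.30	G2M.SYN.31	G2M.SYN.32	G2M.SYN.33	G2M.SYN.34	G2M.SYN.35	G2M.SYN.36	G2M.SYN.37	G2M.SYN.38	G2M.SYN.39	G2M.SYN.40	G2M.SYN.41	G2M.SYN.42	G2M.SYN.43	G2M.SYN.44	G2M.SYN.45	G2M.SYN.46	G2M.SYN.47	G2M.SYN.48	G2M.SYN.49	G2M.SYN.50	G2M.SYN.51	G2M.SYN.52	G2M.SYN.53	G2M.SYN.54
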