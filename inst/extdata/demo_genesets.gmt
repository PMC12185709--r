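target_module_a	synthetic demo set: first half of the planted crosstalk-target block	g0451	g0452	g0453	g0454	g0455	g0456	g0457	g0458	g0459	g0460	g0461	g0462	g0463	g0464	g0465	g0466	g0467	g0468	g0469	g0470	g0471	g0472	g0473	g0474	g0475	g0476	g0477	g0478	g0479	g0480	g0481	g0482	g0483	g0484	g0485	g0486	g0487	g0488	g0489	g0490
target_module_b	synthetic demo set: second half of the planted crosstalk-target block	g0491	g0492	g0493	g0494	g0495	g0496	g0497	g0498	g0499	g0500	g0501	g0502	g0503	g0504	g0505	g0506	g0507	g0508	g0509	g0510	g0511	g0512	g0513	g0514	g0515	g0516	g0517	g0518	g0519	g0520	g0521	g0522	g0523	g0524	g0525	g0526	g0527	g0528	g0529	g0530
male_biased_module	synthetic demo set: planted male-biased genes	g0051	g0052	g0053	g0054	g0055	g0056	g0057	g0058	g0059	g0060	g0061	g0062	g0063	g0064	g0065	g0066	g0067	g0068	g0069	g0070	g0071	g0072	g0073	g0074	g0075	g0076	g0077	g0078	g0079	g0080	g0081	g0082	g0083	g0084	g0085	g0086	g0087	g0088	g0089	g0090
random_module	synthetic demo set: genes with no planted structure	g1001	g1002	g1003	g1004	g1005	g1006	g1007	g1008	g1009	g1010	g1011	g1012	g1013	g1014	g1015	g1016	g1017	g1018	g1019	g1020	g1021	g1022	g1023	g1024	g1025	g1026	g1027	g1028	g1029	g1030	g1031	g1032	g1033	g1034	g1035	g1036	g1037	g1038	g1039	g1040
housekeeping_module	synthetic demo set: genes with no planted structure	g1901	g1902	g1903	g1904	g1905	g1906	g1907	g1908	g1909	g1910	g1911	g1912	g1913	g1914	g1915	g1916	g1917	g1918	g1919	g1920	g1921	g1922	g1923	g1924	g1925	g1926	g1927	g1928	g1929	g1930	g1931	g1932	g1933	g1934	g1935	g1936	g1937	g1938	g1939	g1940	g1941	g1942	g1943	g1944	g1945	g1946	g1947	g1948	g1949	g1950
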