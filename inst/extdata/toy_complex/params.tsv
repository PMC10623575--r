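atom_id	charge	lj_rmin_half	lj_epsilon	gb_radius	gb_screen	atom_type
1	-0.235633790201973	1.68566409237683	0.186931388638914	1.3677405905677	0.898530951607972	N
2	-0.129018553707283	1.77965266034007	0.0940405059140176	1.24125406409148	0.809206844014116	O
3	0.0717109100078233	1.6948330456391	0.118859858938959	1.64960178097244	0.807182914386503	O
4	0.407065336650703	1.44897408112884	0.0998592011281289	1.81338844888378	0.751219620276242	C
5	-0.299460522306617	1.96189865488559	0.147630570060574	1.74524027421139	0.855867770011537	S
6	0.397247231623624	1.83477339055389	0.0887025171075948	1.75811617812142	0.801701188059524	H
7	0.443532815261278	1.93539188858122	0.121781787241343	1.51869211753365	0.812010561078787	H
8	0.159655339142773	1.38635490071028	0.164946600596886	1.48705885743257	0.757358120391145	C
9	0.127971590554807	1.87896875683218	0.0626370371552184	1.76760916993953	0.761158465691842	S
10	-0.439356182876509	1.62901954371482	0.181298199505545	1.62345330319367	0.827228159336373	S
11	-0.295167878444772	1.95675703529269	0.100860940676648	1.658306749654	0.823476995690726	C
12	-0.324585700815078	1.81764815505594	0.175916052528191	1.44723809035495	0.733871588450857	O
13	0.18588039331371	1.92634620983154	0.102002523373812	1.38918210212141	0.726397304325365	O
14	-0.117038735130336	1.74242904931307	0.100066239619628	1.89487884282134	0.835703188595362	O
15	0.268698966654483	1.72377566415817	0.12145268676104	1.64344528510701	0.887150735934265	O
16	-0.00344321125885472	1.93148498535156	0.183829750376754	1.3492456946522	0.827656636023894	H
17	0.216476054920349	1.31866496186703	0.179650920594577	1.29056064365432	0.820962134641595	C
18	0.49076364148641	1.68178405202925	0.108498431521002	1.53468262401875	0.814684990304522	C
19	-0.121107273909729	1.88585099093616	0.166598104825243	1.84685212888289	0.897317140297964	H
20	0.276302767975722	1.85418524518609	0.194092699582689	1.61913267700002	0.811375528019853	N
21	0.433562777761836	1.68209569770843	0.115198922716081	1.88331948644482	0.842901854161173	C
22	-0.288999932061415	1.98896758146584	0.15687720180722	1.71225475831889	0.828277419176884	N
23	0.150531312741805	1.65047768577933	0.109999155334663	1.44970883845817	0.762996361996047	O
24	-0.375587357382756	1.49583782162517	0.0988028227817267	1.50203158338554	0.766469866801053	H
25	-0.275971480257188	1.35654323771596	0.163563072204124	1.30374809247442	0.851275732205249	C
26	-0.157078056440999	1.37957292813808	0.0804038382717408	1.2091543028364	0.801462749652564	O
27	-0.529801815825825	1.5530173657462	0.156668183370493	1.70089624626562	0.751522818314843	S
28	-0.160804191914697	1.71490741055459	0.0682537881541066	1.27222896502353	0.854405688531697	O
29	0.32649869673575	1.82960406113416	0.0868232770939358	1.51239904402755	0.738897775271907	H
30	-0.20284315229704	1.62546414975077	0.071495656913612	1.64807073159609	0.875618090825155	N
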